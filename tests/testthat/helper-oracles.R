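# Independent oracles and small fixture builders used across the suite.

# Brute-force Hochberg step-up: adjusted p for the hypothesis with sorted
# rank i is min over j >= i of (m - j + 1) * p_(j), capped at 1. A direct
# double-loop evaluation of the step-up definition, independent of
# stats::p.adjust.
hochberg_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(vapply(i:m, function(j) (m - j + 1) * ps[j], numeric(1))))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Exhaustive two-sample KS statistic: maximum absolute ECDF difference
# evaluated on the pooled support.
ks_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Welch statistic evaluated directly from the defining formula.
welch_oracle <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# A raga spec with weight only on the given pitch classes (cents labels),
# equal-tempered, no drone (convenient for estimator tests).
flat_spec <- function(cents, name = "test", ...) {
  w <- setNames(numeric(12), as.character(seq(0, 1100, by = 100)))
  w[as.character(cents)] <- 1 / length(cents)
  raga_spec(name, w, cent_offsets = rep(0, 12), ...)
}

# A small fully crossed stimulus table.
toy_stimuli <- function(n_ragas = 12) {
  tonality <- seq(0, 1.4, length.out = n_ragas)
  data.frame(raga = rep(sprintf("r%02d", seq_len(n_ragas)), each = 2),
             mode = rep(c("alaap", "gat"), n_ragas),
             tonality = rep(tonality, each = 2))
}

toy_features <- function(stimuli) {
  data.frame(raga = stimuli$raga, mode = stimuli$mode,
             tonality_ratio = stimuli$tonality)
}

# Hand-assembled rating table (fully crossed) for analysis unit tests.
manual_ratings <- function(df) {
  df$familiarity <- df$familiarity %||% 2L
  tibble::tibble(participant_id = df$participant_id, group = df$group,
                 familiarity = df$familiarity, raga = df$raga,
                 mode = df$mode, emotion = df$emotion,
                 rating = as.integer(df$rating))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
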