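# Between-group comparison of emotion ratings: mean matrices, modal
# labels, distribution tests, the 192-comparison family with Hochberg
# correction, and the universality verdict.

validate_rating_table <- function(ratings) {
  need <- c("participant_id", "group", "familiarity", "raga", "mode",
            "emotion", "rating")
  if (!all(need %in% names(ratings)))
    stop("rating table must have columns: ", paste(need, collapse = ", "))
  if (!all(ratings$group %in% GROUPS))
    stop("group must be one of: ", paste(GROUPS, collapse = ", "))
  if (!all(ratings$mode %in% c("alaap", "gat")))
    stop("mode must be 'alaap' or 'gat'")
  if (!all(ratings$emotion %in% EMOTIONS))
    stop("emotion must be one of the 8 canonical labels")
  if (!all(ratings$rating %in% 0:4))
    stop("ratings must be integers in 0..4")
  invisible(ratings)
}

excerpt_levels <- function(ratings) {
  ragas <- sort(unique(ratings$raga))
  as.vector(t(outer(ragas, c("alaap", "gat"), paste, sep = "_")))
}

#' Keep only participants who rated enough excerpts
#'
#' Mirrors the survey inclusion rule: raters could opt out after two
#' blocks, so only participants with at least `min_excerpts` rated
#' excerpts are analyzed.
#'
#' @param ratings a rating table.
#' @param min_excerpts inclusion threshold (default 12).
#' @return the filtered rating table.
#' @export
filter_participants <- function(ratings, min_excerpts = 12) {
  validate_rating_table(ratings)
  n_exc <- tapply(paste(ratings$raga, ratings$mode),
                  ratings$participant_id,
                  function(x) length(unique(x)))
  keep <- names(n_exc)[n_exc >= min_excerpts]
  ratings[ratings$participant_id %in% keep, , drop = FALSE]
}

#' Per-group mean rating matrix (excerpt x emotion)
#'
#' Each cell is the arithmetic mean of that group's participant ratings
#' for one excerpt (raga x mode) and one emotion; with 12 ragas in both
#' modes the matrix is 24 x 8. Cells with no raters are `NA` with a zero
#' count.
#'
#' @param ratings a rating table.
#' @param group `"E"` or `"NE"`.
#' @return object of class `mean_rating_matrix`: `group`, `means`
#'   (excerpt x emotion), `n` (rater counts).
#' @export
build_mean_matrix <- function(ratings, group) {
  validate_rating_table(ratings)
  group <- match.arg(group, GROUPS)
  d <- ratings[ratings$group == group, , drop = FALSE]
  if (nrow(d) == 0L) stop("no ratings for group ", group)
  exc <- factor(paste(d$raga, d$mode, sep = "_"),
                levels = excerpt_levels(ratings))
  emo <- factor(d$emotion, levels = EMOTIONS)
  means <- tapply(d$rating, list(exc, emo), mean)
  n <- tapply(d$rating, list(exc, emo), length)
  n[is.na(n)] <- 0L
  structure(list(group = group, means = means, n = n),
            class = "mean_rating_matrix")
}

#' @export
print.mean_rating_matrix <- function(x, ...) {
  cat(sprintf("Mean rating matrix, group %s (%d excerpts x %d emotions)\n",
              x$group, nrow(x$means), ncol(x$means)))
  print(round(x$means, 2))
  invisible(x)
}

#' @export
plot.mean_rating_matrix <- function(x, ...) {
  m <- x$means[rev(seq_len(nrow(x$means))), , drop = FALSE]
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  axes = FALSE, xlab = "", ylab = "",
                  main = paste("Group", x$group), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.5)
  invisible(x)
}

#' Most frequently occurring emotion label for an excerpt
#'
#' With `method = "participant_argmax"` (default) each participant votes
#' for their maximum-rated emotion(s) for the excerpt; the label(s) with
#' the most votes are returned (ties as a set). With `method = "mean"` the
#' label(s) maximizing the group's mean rating are returned.
#'
#' @param ratings a rating table.
#' @param raga,mode excerpt identifier.
#' @param group `"E"` or `"NE"`.
#' @param method `"participant_argmax"` or `"mean"`.
#' @return character vector of one or more tied labels.
#' @export
modal_label <- function(ratings, raga, mode, group,
                        method = c("participant_argmax", "mean")) {
  validate_rating_table(ratings)
  method <- match.arg(method)
  group <- match.arg(group, GROUPS)
  d <- ratings[ratings$group == group & ratings$raga == raga &
                 ratings$mode == mode, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no ratings for excerpt ", raga, "_", mode, " in group ", group)
  if (method == "mean") {
    m <- tapply(d$rating, factor(d$emotion, levels = EMOTIONS), mean)
    return(names(m)[!is.na(m) & m >= max(m, na.rm = TRUE) - 1e-12])
  }
  votes <- setNames(numeric(length(EMOTIONS)), EMOTIONS)
  for (p in split(d, d$participant_id)) {
    top <- p$emotion[p$rating == max(p$rating)]
    votes[top] <- votes[top] + 1
  }
  names(votes)[votes >= max(votes) - 1e-12]
}

#' Cross-group agreement of modal labels over all excerpts
#'
#' The two groups "agree" on an excerpt when their modal-label sets
#' intersect.
#'
#' @param ratings a rating table.
#' @param method passed to [modal_label()].
#' @return [tibble::tibble()] with one row per excerpt: `raga`, `mode`,
#'   `label_e`, `label_ne` (tied sets collapsed with "/"), `agree`;
#'   attribute `n_agree` gives the agreement count.
#' @export
modal_label_agreement <- function(ratings,
                                  method = c("participant_argmax", "mean")) {
  method <- match.arg(method)
  ragas <- sort(unique(ratings$raga))
  rows <- list()
  for (r in ragas) for (m in c("alaap", "gat")) {
    le <- modal_label(ratings, r, m, "E", method)
    ln <- modal_label(ratings, r, m, "NE", method)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      raga = r, mode = m,
      label_e = paste(le, collapse = "/"),
      label_ne = paste(ln, collapse = "/"),
      agree = length(intersect(le, ln)) > 0)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_agree") <- sum(out$agree)
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of rating distributions
#'
#' Compares the per-participant rating distributions of the two groups for
#' one excerpt and emotion. Ratings are discrete (0-4), so ties are
#' pervasive and the asymptotic p-value is used; treat it as approximate.
#'
#' @param ratings a rating table.
#' @param raga,mode excerpt identifier.
#' @param emotion one of the 8 canonical labels.
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_compare <- function(ratings, raga, mode, emotion) {
  validate_rating_table(ratings)
  d <- ratings[ratings$raga == raga & ratings$mode == mode &
                 ratings$emotion == emotion, , drop = FALSE]
  x <- d$rating[d$group == "E"]
  y <- d$rating[d$group == "NE"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 ratings per group")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# Welch t robust to the zero-variance cells a discrete instrument can
# produce (t.test() errors on essentially-constant data).
welch_safe <- function(x, y) {
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  if (!is.finite(se) || se == 0) {
    d <- mean(x) - mean(y)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                p.value = if (d == 0) 1 else 0))
  }
  tt <- t.test(x, y)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

wilcox_safe <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = p)
}

#' All between-group intensity comparisons with Hochberg correction
#'
#' One comparison per excerpt x emotion (8 emotions x 12 ragas x 2 modes =
#' 192 on the full design), run as Welch t-tests and/or Wilcoxon rank-sum
#' tests with continuity correction, two-sided. Within each test family
#' the p-values are jointly Hochberg-adjusted.
#'
#' @param ratings a rating table with both groups present for every cell.
#' @param tests which families to run.
#' @param alpha significance level for the `significant` flag.
#' @return [tibble::tibble()] with columns `raga`, `mode`, `emotion`,
#'   `test`, `statistic`, `p`, `p_adj`, `significant`.
#' @export
compare_intensities <- function(ratings, tests = c("welch", "wilcoxon"),
                                alpha = 0.05) {
  validate_rating_table(ratings)
  tests <- match.arg(tests, several.ok = TRUE)
  key <- paste(ratings$raga, ratings$mode, ratings$emotion, sep = "\r")
  by_cell <- split(ratings[c("group", "rating")], key)
  cells <- do.call(rbind, strsplit(names(by_cell), "\r", fixed = TRUE))
  fams <- list()
  for (test in tests) {
    res <- vapply(by_cell, function(d) {
      x <- d$rating[d$group == "E"]
      y <- d$rating[d$group == "NE"]
      if (length(x) == 0L || length(y) == 0L)
        stop("both groups must be represented in every cell")
      r <- if (test == "welch") welch_safe(x, y) else wilcox_safe(x, y)
      c(r$statistic, r$p.value)
    }, numeric(2))
    fams[[test]] <- tibble::tibble(
      raga = cells[, 1], mode = cells[, 2], emotion = cells[, 3],
      test = test, statistic = unname(res[1, ]), p = unname(res[2, ]),
      p_adj = unname(hochberg_adjust(res[2, ])))
  }
  out <- dplyr::bind_rows(fams)
  out$significant <- out$p_adj < alpha
  out[order(out$test, out$raga, out$mode, out$emotion), ]
}

#' Hochberg step-up adjustment of p-values
#'
#' Step-up familywise-error control: sort ascending, set
#' `adj(m) = p(m)`, `adj(i) = min(adj(i+1), (m-i+1) p(i))`, cap at 1,
#' return in input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
hochberg_adjust <- function(p) {
  stopifnot(is.numeric(p), length(p) >= 1L)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "hochberg")
}

#' Universality verdict from a family of adjusted p-values
#'
#' Universality of the emotional response is declared when strictly more
#' than half of the adjusted p-values exceed `alpha`.
#'
#' @param p_adj adjusted p-values (non-empty).
#' @param alpha significance level (default 0.05).
#' @return list with `universal` (logical), `n_significant`, `n_total`,
#'   `fraction_significant`.
#' @export
universality_verdict <- function(p_adj, alpha = 0.05) {
  stopifnot(is.numeric(p_adj), length(p_adj) >= 1L,
            all(is.finite(p_adj)))
  n_sig <- sum(p_adj <= alpha)
  list(universal = mean(p_adj > alpha) > 0.5,
       n_significant = n_sig,
       n_total = length(p_adj),
       fraction_significant = n_sig / length(p_adj))
}

#' Welch t-test from summary statistics
#'
#' The Welch statistic and Satterthwaite degrees of freedom computed from
#' group means, standard deviations and sizes, as used to compare
#' familiarity scores between groups.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `statistic`, `df`, `p.value` (two-sided).
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 > 1, n2 > 1, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) stop("both groups have zero variance")
  t_stat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t_stat, df = df,
       p.value = 2 * pt(-abs(t_stat), df))
}
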