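# Between-group rating analysis: mean matrices, modal labels, KS and
# Welch/Wilcoxon families, Hochberg correction, universality rule.

small_table <- function() {
  stim <- toy_stimuli(2)
  params <- rating_sim_params(n_participants = c(E = 12, NE = 10),
                              completion_probs = c(0, 0, 1))
  simulate_ratings(params, stim, seed = 3)
}

test_that("mean matrix averages the group's raters cell-wise", {
  df <- expand.grid(participant_id = c("E001", "E002"), group = "E",
                    raga = "r01", mode = c("alaap", "gat"),
                    emotion = EMOTIONS, stringsAsFactors = FALSE)
  df$familiarity <- 2L
  df$rating <- ifelse(df$participant_id == "E001", 1L, 3L)
  mm <- build_mean_matrix(manual_ratings(df), "E")
  expect_true(all(mm$means == 2))
  expect_true(all(mm$n == 2))
  # single participant: matrix equals their ratings
  one <- df[df$participant_id == "E001", ]
  mm1 <- build_mean_matrix(manual_ratings(one), "E")
  expect_true(all(mm1$means == 1))
})

test_that("the full design yields a 24 x 8 matrix per group", {
  rt <- simulate_ratings(
    rating_sim_params(n_participants = c(E = 6, NE = 6),
                      completion_probs = c(0, 0, 1)),
    toy_stimuli(12), seed = 2)
  mm <- build_mean_matrix(rt, "NE")
  expect_equal(dim(mm$means), c(24L, 8L))
  expect_true(all(mm$means >= 0 & mm$means <= 4))
})

test_that("modal label returns the most-voted label, with ties as a set", {
  base <- expand.grid(participant_id = sprintf("E%03d", 1:4), group = "E",
                      raga = "r01", mode = "alaap", emotion = EMOTIONS,
                      stringsAsFactors = FALSE)
  base$familiarity <- 2L
  base$rating <- 1L
  base$rating[base$emotion == "calm"] <- 4L
  rt <- manual_ratings(base)
  expect_identical(modal_label(rt, "r01", "alaap", "E"), "calm")
  # two-way tie: half the raters peak on happy instead
  tied <- base
  tied$rating <- 1L
  tied$rating[tied$emotion == "calm" &
                tied$participant_id %in% c("E001", "E002")] <- 4L
  tied$rating[tied$emotion == "happy" &
                tied$participant_id %in% c("E003", "E004")] <- 4L
  expect_setequal(modal_label(manual_ratings(tied), "r01", "alaap", "E"),
                  c("calm", "happy"))
  expect_error(modal_label(rt, "r09", "gat", "E"), "no ratings")
})

test_that("modal labels mostly agree when both groups share one process", {
  rt <- simulate_ratings(
    default_sim_params("null", n_participants = c(E = 80, NE = 80)),
    toy_stimuli(12), seed = 7)
  agreement <- modal_label_agreement(rt)
  expect_equal(nrow(agreement), 24L)
  expect_gte(attr(agreement, "n_agree"), 20L)
})

test_that("KS comparison equals the exhaustive ECDF oracle", {
  mk <- function(xe, xne) {
    ne <- length(xe); nn <- length(xne)
    manual_ratings(data.frame(
      participant_id = c(sprintf("E%03d", seq_len(ne)),
                         sprintf("N%03d", seq_len(nn))),
      group = rep(c("E", "NE"), c(ne, nn)), familiarity = 2L,
      raga = "r01", mode = "gat", emotion = "sad",
      rating = c(xe, xne)))
  }
  r <- ks_compare(mk(c(0L, 1L, 2L), c(2L, 3L, 4L)), "r01", "gat", "sad")
  expect_equal(r$statistic, ks_oracle(c(0, 1, 2), c(2, 3, 4)))
  expect_equal(ks_compare(mk(c(1L, 2L, 3L), c(1L, 2L, 3L)),
                          "r01", "gat", "sad")$statistic, 0)
  expect_equal(ks_compare(mk(rep(0L, 4), rep(4L, 4)),
                          "r01", "gat", "sad")$statistic, 1)
  # property: oracle agreement over random small discrete samples
  set.seed(8)
  for (i in 1:50) {
    xe <- sample(0:4, sample(2:6, 1), replace = TRUE)
    xne <- sample(0:4, sample(2:6, 1), replace = TRUE)
    expect_equal(ks_compare(mk(xe, xne), "r01", "gat", "sad")$statistic,
                 ks_oracle(xe, xne))
  }
})

test_that("intensity comparisons produce the full Hochberg-corrected family", {
  rt <- simulate_ratings(
    rating_sim_params(n_participants = c(E = 10, NE = 10),
                      completion_probs = c(0, 0, 1)),
    toy_stimuli(12), seed = 5)
  comps <- compare_intensities(rt)
  expect_equal(sum(comps$test == "welch"), 192L)
  expect_equal(sum(comps$test == "wilcoxon"), 192L)
  expect_true(all(comps$p_adj >= comps$p - 1e-12))
  expect_true(all(comps$p_adj <= 1))
  # per-family adjustment matches applying Hochberg to that family alone
  fam <- comps[comps$test == "welch", ]
  expect_equal(fam$p_adj, hochberg_adjust(fam$p))
})

test_that("welch statistic matches its formula, identical samples give t = 0", {
  x <- c(0L, 1L, 2L, 3L)
  df <- manual_ratings(data.frame(
    participant_id = c(sprintf("E%03d", 1:4), sprintf("N%03d", 1:4)),
    group = rep(c("E", "NE"), each = 4), familiarity = 2L,
    raga = "r01", mode = "alaap", emotion = "happy",
    rating = c(x, x)))
  comps <- compare_intensities(df, tests = "welch")
  expect_equal(comps$statistic, 0)
  expect_equal(comps$p, 1)
  # formula check on the familiarity-style summary comparison
  w <- welch_t_summary(2.86, 1.09, 141, 1.99, 1.02, 111)
  expect_equal(w$statistic, 6.5, tolerance = 0.01)
  expect_equal(w$df, 245, tolerance = 0.01)
  expect_lt(w$p.value, 1e-5)
})

test_that("hochberg adjustment equals the step-up oracle on worked examples", {
  expect_equal(hochberg_adjust(c(0.01, 0.04)), hochberg_oracle(c(0.01, 0.04)))
  expect_equal(hochberg_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(hochberg_adjust(rep(0.03, 3)), rep(0.03, 3))
  expect_equal(hochberg_adjust(0.7), 0.7)
  expect_error(hochberg_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:25) {
    p <- round(runif(sample(1:10, 1)), 3)
    expect_equal(hochberg_adjust(p), hochberg_oracle(p))
  }
})

test_that("universality verdict applies the strict majority rule", {
  v <- universality_verdict(c(rep(0.01, 18), rep(0.6, 174)))
  expect_true(v$universal)
  expect_equal(v$fraction_significant, 18 / 192)
  expect_true(universality_verdict(c(rep(0.01, 95), rep(0.6, 97)))$universal)
  expect_false(universality_verdict(c(rep(0.01, 96), rep(0.6, 96)))$universal)
  expect_error(universality_verdict(numeric(0)))
})

test_that("participant inclusion filter drops sparse raters", {
  rt <- small_table()
  # a participant who rated only one excerpt
  extra <- manual_ratings(data.frame(
    participant_id = "E999", group = "E", familiarity = 1L, raga = "r01",
    mode = "alaap", emotion = EMOTIONS, rating = 1L))
  both <- dplyr::bind_rows(rt, extra)
  kept <- filter_participants(both, min_excerpts = 4)
  expect_false("E999" %in% kept$participant_id)
  expect_true(all(unique(rt$participant_id) %in% kept$participant_id))
})
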