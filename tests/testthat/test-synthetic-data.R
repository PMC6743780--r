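# The stimulus generator: determinism, ground-truth contracts, and the
# rating simulator's linear structure.

test_that("regenerating with the same seed is byte-identical", {
  spec <- flat_spec(c(0, 300, 700), drone_amp = 0.25)
  mode <- mode_spec("gat", duration_s = 8)
  a <- generate_raga_audio(spec, mode, seed = 42)
  b <- generate_raga_audio(spec, mode, seed = 42)
  expect_identical(a$wave, b$wave)
  expect_identical(a$pitch_track, b$pitch_track)
  c <- generate_raga_audio(spec, mode, seed = 43)
  expect_false(identical(a$wave, c$wave))
})

test_that("an all-tonic raga yields a pitch track at 0 cents throughout", {
  spec <- flat_spec(0)
  a <- generate_raga_audio(spec, mode_spec("alaap", duration_s = 20),
                           seed = 1, render_audio = FALSE)
  v <- a$pitch_track[a$pitch_track$voiced, ]
  expect_gt(nrow(v), 0)
  expect_true(all(abs(v$cents %% 1200) < 1e-9))
})

test_that("a major-only swara set gives tonality ratio zero downstream", {
  spec <- flat_spec(c(0, 200, 400, 500, 700, 900, 1100))
  a <- generate_raga_audio(spec, mode_spec("alaap", duration_s = 30),
                           seed = 2, render_audio = FALSE)
  expect_equal(as.numeric(tonality_ratio(a$pitch_track)), 0)
})

test_that("gat onset count tracks event_rate x duration", {
  a <- generate_raga_audio(flat_spec(c(0, 700)),
                           mode_spec("gat", event_rate = 1.5,
                                     duration_s = 60),
                           seed = 3, render_audio = FALSE)
  expect_lt(abs(nrow(a$melody) - 90), 5)
})

test_that("empty swara sets and zero durations are rejected", {
  expect_error(flat_spec(integer(0)), "empty")
  expect_error(mode_spec("alaap", duration_s = 0), "positive")
})

test_that("pitch-track swara occupancy converges to swara_weights", {
  spec <- default_raga_set()[["raga09"]]
  for (m in c("alaap", "gat")) {
    a <- generate_raga_audio(spec, mode_spec(m, duration_s = 180),
                             seed = 11, render_audio = FALSE)
    prof <- fold_octaves(interval_histogram(a$pitch_track))
    tv <- 0.5 * sum(abs(prof$proportions - spec$swara_weights))
    expect_lt(tv, 0.05)
  }
})

test_that("simulated ratings follow the linear predictor exactly when noise-free", {
  stim <- data.frame(raga = c("a", "b", "c"), mode = "alaap",
                     tonality = c(0, 0.5, 1))
  co <- default_coefficients()
  co$intercept <- 2
  co$b_tonality <- 0
  co$b_rhythm <- 0
  co$b_familiarity <- 0
  params <- rating_sim_params(co, noise_sd = 0,
                              n_participants = c(E = 5, NE = 5),
                              completion_probs = c(0, 0, 1))
  rt <- simulate_ratings(params, stim, seed = 1)
  expect_true(all(rt$rating == 2L))

  co$b_tonality <- 2  # steep enough that rounding preserves strictness
  params2 <- rating_sim_params(co, noise_sd = 0,
                               n_participants = c(E = 5, NE = 5),
                               completion_probs = c(0, 0, 1))
  rt2 <- simulate_ratings(params2, stim, seed = 1)
  m <- tapply(rt2$rating, rt2$raga, mean)
  expect_true(all(diff(m[c("a", "b", "c")]) > 0))
})

test_that("rating simulator validates inputs and is deterministic", {
  expect_error(rating_sim_params(n_participants = c(E = 0, NE = 5)),
               "at least 1")
  stim <- toy_stimuli(4)
  params <- rating_sim_params(n_participants = c(E = 8, NE = 8))
  expect_error(simulate_ratings(params, stim[0, ], seed = 1),
               "at least one stimulus")
  expect_identical(simulate_ratings(params, stim, seed = 9),
                   simulate_ratings(params, stim, seed = 9))
  rt <- simulate_ratings(params, stim, seed = 9)
  expect_true(all(rt$rating %in% 0:4))
  expect_true(all(rt$familiarity %in% 0:4))
})

test_that("least squares on noise-free simulated group means recovers the betas", {
  stim <- toy_stimuli(12)
  # with noise_sd = 0 ratings are round(mu), so use a coefficient set and
  # tonality grid for which the linear predictor is integer-valued
  co <- default_coefficients()
  co$intercept <- 1
  co$b_tonality <- 1   # tonality grid below chosen integer-friendly
  co$b_rhythm <- 1
  co$b_familiarity <- 0
  stim$tonality <- rep(seq(0, 2, length.out = 12), each = 2)[seq_len(nrow(stim))]
  stim$tonality <- round(stim$tonality)  # 0, 1 or 2: mu stays integral
  params <- rating_sim_params(co, noise_sd = 0,
                              n_participants = c(E = 10, NE = 10),
                              completion_probs = c(0, 0, 1))
  rt <- simulate_ratings(params, stim, seed = 4)
  d <- aggregate(rating ~ raga + mode, data = rt[rt$group == "E", ], mean)
  d <- merge(d, unique(stim[c("raga", "mode", "tonality")]))
  d$rhythm <- as.integer(d$mode == "gat")
  fit <- lm(rating ~ tonality + rhythm, data = d)
  expect_equal(unname(coef(fit)), c(1, 1, 1), tolerance = 1e-6)
})
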