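# Tonality descriptors: cents conversion, interval histogram, octave
# folding, the m/M ratio, and the autocorrelation pitch estimator.

test_that("hz_to_cents matches its defining formula and invariants", {
  expect_identical(hz_to_cents(261.5, 261.5), 0)
  expect_identical(hz_to_cents(523.0, 261.5), 1200)
  expect_equal(hz_to_cents(277.18, 261.5), 100.8147, tolerance = 1e-4)
  expect_error(hz_to_cents(-1, 261.5), "positive")
  expect_error(hz_to_cents(440, 0), "positive")
  # octave additivity and symmetry across a range of frequencies
  f <- c(82.4, 110, 261.5, 329.6, 440, 987.8)
  expect_equal(hz_to_cents(2 * f, 261.5), hz_to_cents(f, 261.5) + 1200)
  expect_equal(hz_to_cents(f, 440), -hz_to_cents(440, f))
  expect_equal(cents_to_hz(hz_to_cents(f, 261.5), 261.5), f)
})

test_that("interval histogram bins, drops and conserves frames as specified", {
  tr <- pitch_track(time_s = seq(0, 0.15, by = 0.03),
                    hz = cents_to_hz(c(0, 0, 0, -1100, 100, 1300), 261.5),
                    tonic_hz = 261.5)
  h <- interval_histogram(tr)
  expect_length(h$counts, 37)
  expect_equal(unname(h$counts[c("-1100", "0", "100", "1300")]),
               c(1L, 3L, 1L, 1L))
  expect_equal(sum(h$counts), h$total_voiced - h$n_dropped)
  # out-of-range frames are dropped and counted
  tr2 <- pitch_track(time_s = c(0, 0.03, 0.06),
                     hz = cents_to_hz(c(0, 2600, -1400), 261.5),
                     tonic_hz = 261.5)
  h2 <- interval_histogram(tr2)
  expect_equal(h2$n_dropped, 2L)
  expect_equal(sum(h2$counts), 1L)
  # unvoiced-only track errors
  tr3 <- pitch_track(time_s = c(0, 0.03), hz = c(NA_real_, NA_real_),
                     tonic_hz = 261.5)
  expect_error(interval_histogram(tr3), "voiced")
})

test_that("octave folding collates pitch classes and conserves totals", {
  cents <- c(rep(-1100, 3), rep(100, 5), rep(1300, 7), rep(0, 2),
             rep(2400, 4))
  tr <- pitch_track(time_s = seq_along(cents) * 0.03,
                    hz = cents_to_hz(cents, 261.5), tonic_hz = 261.5)
  prof <- fold_octaves(interval_histogram(tr))
  expect_equal(unname(prof$counts["100"]), 15)   # komal re: 3 + 5 + 7
  expect_equal(unname(prof$counts["0"]), 6)      # tonic class incl. +2 octaves
  expect_equal(sum(prof$counts), length(cents))
  expect_equal(sum(prof$proportions), 1)
})

test_that("tonality ratio implements the minor/major occupancy contrast", {
  # mass only on major bins -> 0
  major <- setNames(numeric(12), as.character(seq(0, 1100, by = 100)))
  major[as.character(c(0, 200, 400, 500, 700, 900, 1100))] <- 1
  expect_equal(as.numeric(tonality_ratio(major)), 0)
  # uniform mass -> 5 minor bins over 7 major bins
  expect_equal(as.numeric(tonality_ratio(rep(1, 12))), 5 / 7)
  # minor-only mass -> undefined, flagged
  minor <- setNames(numeric(12), as.character(seq(0, 1100, by = 100)))
  minor[as.character(c(100, 300, 600, 800, 1000))] <- 1
  r <- tonality_ratio(minor)
  expect_true(attr(r, "undefined"))
  expect_identical(as.numeric(r), Inf)
  # invariance to uniform rescaling
  w <- c(2, 1, 0, 3, 1, 0, 2, 5, 0, 1, 1, 4)
  expect_equal(as.numeric(tonality_ratio(w)),
               as.numeric(tonality_ratio(10 * w)))
})

test_that("pitch estimator recovers pure tones and flags silence", {
  sr <- 22050
  t <- seq_len(2 * sr) / sr
  pt <- estimate_pitch_track(sin(2 * pi * 440 * t), sr, tonic_hz = 261.5)
  expect_gt(mean(pt$voiced), 0.9)
  err <- pt$cents[pt$voiced] - hz_to_cents(440, 261.5)
  expect_true(all(abs(err) < 10))
  silent <- estimate_pitch_track(numeric(2 * sr), sr, tonic_hz = 261.5)
  expect_equal(sum(silent$voiced), 0)
})

test_that("pitch estimator occupancy matches ground truth on a two-note melody", {
  spec <- flat_spec(c(0, 700), drone_amp = 0, octave_weights = c(0, 1, 0))
  a <- generate_raga_audio(spec, mode_spec("gat", duration_s = 20,
                                           pulse_track = FALSE),
                           seed = 5)
  est <- estimate_pitch_track(a$wave, a$sample_rate, spec$tonic_hz)
  prof <- fold_octaves(interval_histogram(est))
  occ <- prof$proportions[c("0", "700")]
  expect_gt(sum(occ), 0.9)               # nearly all frames on the two swaras
  expect_lt(abs(occ[["0"]] - 0.5), 0.12) # approximately 50/50 split
  truth <- fold_octaves(interval_histogram(a$pitch_track))$proportions
  expect_lt(max(abs(prof$proportions - truth)), 0.12)
})
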