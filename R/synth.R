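# Synthetic raga-like stimuli: drone + melody generator with known ground
# truth. The melody is a sequence of discrete notes drawn from a prescribed
# swara set; the drone sustains the tonic throughout.

#' Five-limit just-intonation deviations from equal temperament
#'
#' Deviation in cents of each of the 12 pitch classes (0, 100, ..., 1100
#' cents above the tonic) when tuned to a five-limit just-intonation scale,
#' as a sarod tuned to just intonation would realize them.
#'
#' @return named numeric vector of length 12 (cents).
#' @export
just_intonation_offsets <- function() {
  setNames(c(0, 11.7, 3.9, 15.6, -13.7, -2.0, -9.8, 2.0, 13.7, -15.6,
             17.6, -11.7),
           as.character(ALL_CENTS))
}

#' Specify a synthetic raga
#'
#' A raga specification: a tonic frequency, sampling weights over the 12
#' pitch classes (swaras, labeled by cents above the tonic), per-swara
#' intonation offsets, and octave placement probabilities.
#'
#' @param name label for the raga.
#' @param swara_weights numeric vector of length 12 (pitch classes 0, 100,
#'   ..., 1100 cents), non-negative with positive sum; normalized to sum 1.
#' @param tonic_hz tonic (Sa) frequency in Hz; default 261.5.
#' @param cent_offsets per-swara deviation in cents from equal temperament,
#'   each strictly less than 50 in magnitude.
#' @param octave_weights probabilities over octaves -1, 0, +1.
#' @param drone_amp drone amplitude relative to the melody (0 disables the
#'   drone).
#' @return object of class `raga_spec`.
#' @export
raga_spec <- function(name, swara_weights, tonic_hz = 261.5,
                      cent_offsets = just_intonation_offsets(),
                      octave_weights = c(0.15, 0.7, 0.15),
                      drone_amp = 0.25) {
  stopifnot(is.character(name), length(name) == 1L,
            is_scalar_number(tonic_hz), tonic_hz > 0,
            is.numeric(swara_weights), length(swara_weights) == 12L,
            all(swara_weights >= 0),
            is.numeric(cent_offsets), length(cent_offsets) == 12L,
            all(abs(cent_offsets) < 50),
            is.numeric(octave_weights), length(octave_weights) == 3L,
            all(octave_weights >= 0), sum(octave_weights) > 0,
            is_scalar_number(drone_amp), drone_amp >= 0)
  if (sum(swara_weights) <= 0)
    stop("swara set is empty: all swara_weights are zero")
  structure(
    list(name = name, tonic_hz = tonic_hz,
         swara_weights = setNames(swara_weights / sum(swara_weights),
                                  as.character(ALL_CENTS)),
         cent_offsets = setNames(cent_offsets, as.character(ALL_CENTS)),
         octave_weights = setNames(octave_weights / sum(octave_weights),
                                   c("-1", "0", "1")),
         drone_amp = drone_amp),
    class = "raga_spec")
}

#' Specify a presentation mode (alaap or gat)
#'
#' The alaap is rhythmically free: exponential inter-onset intervals, no
#' percussion. The gat is pulsed: an isochronous onset grid with small
#' timing jitter plus a percussive click layer on the beat.
#'
#' @param mode `"alaap"` or `"gat"`.
#' @param event_rate notes per second (defaults: alaap 0.5, gat 1.5).
#' @param timing_jitter jitter as a fraction of the inter-onset interval,
#'   in \[0, 1\] (defaults: alaap 0.6, gat 0.05).
#' @param pulse_track add a percussive click layer on the beat (default:
#'   alaap `FALSE`, gat `TRUE`).
#' @param duration_s excerpt duration in seconds (default 180, the length
#'   of a survey excerpt).
#' @return object of class `mode_spec`.
#' @export
mode_spec <- function(mode = c("alaap", "gat"), event_rate = NULL,
                      timing_jitter = NULL, pulse_track = NULL,
                      duration_s = 180) {
  mode <- match.arg(mode)
  if (is.null(event_rate)) event_rate <- if (mode == "alaap") 0.5 else 1.5
  if (is.null(timing_jitter)) timing_jitter <- if (mode == "alaap") 0.6 else 0.05
  if (is.null(pulse_track)) pulse_track <- mode == "gat"
  stopifnot(is_scalar_number(event_rate), event_rate > 0,
            is_scalar_number(timing_jitter),
            timing_jitter >= 0, timing_jitter <= 1,
            is.logical(pulse_track), length(pulse_track) == 1L,
            is_scalar_number(duration_s))
  if (duration_s <= 0) stop("duration_s must be positive")
  structure(list(mode = mode, event_rate = event_rate,
                 timing_jitter = timing_jitter, pulse_track = pulse_track,
                 duration_s = duration_s),
            class = "mode_spec")
}

#' Minor-to-major ratio implied by a raga's swara weights
#'
#' The m/M ratio the rendered melody is designed to realize: summed weight
#' on the five komal (minor) pitch classes over summed weight on the seven
#' shuddh (major) classes.
#'
#' @param spec a [raga_spec()].
#' @return non-negative ratio, `Inf` if the major classes carry no weight.
#' @export
implied_tonality <- function(spec) {
  stopifnot(inherits(spec, "raga_spec"))
  w <- spec$swara_weights
  m <- sum(w[as.character(MINOR_CENTS)])
  M <- sum(w[as.character(MAJOR_CENTS)])
  if (M <= 0) return(Inf)
  m / M
}

# Duration-weighted quota assignment of swaras to notes: process notes
# longest-first, each to the pitch class with the largest remaining time
# deficit. Keeps the rendered time share of every class within a small
# fraction of its target weight (a rendition presents the prescribed swaras
# in balanced proportion, as a raga performance does).
assign_swaras <- function(durations, weights) {
  idx <- which(weights > 0)
  if (length(idx) == 0L) stop("swara set is empty")
  target <- weights[idx] * sum(durations)
  assigned <- numeric(length(idx))
  out <- integer(length(durations))
  for (i in order(durations, decreasing = TRUE)) {
    j <- which.max(target - assigned)
    out[i] <- idx[j]
    assigned[j] <- assigned[j] + durations[i]
  }
  out
}

# Draw onset times and note pitches for one rendition. RNG must already be
# seeded by the caller. Notes are legato: each sustains to the next onset.
generate_melody <- function(spec, mode) {
  dur <- mode$duration_s
  rate <- mode$event_rate
  if (mode$mode == "alaap") {
    n_max <- ceiling(dur * rate * 3) + 10L
    ioi <- pmin(rexp(n_max, rate), 3 / rate)  # cap pathological gaps
    onsets <- cumsum(c(0, ioi))
    onsets <- onsets[onsets < dur]
  } else {
    grid <- seq(0, dur - 1e-9, by = 1 / rate)
    onsets <- grid + runif(length(grid), -0.5, 0.5) * mode$timing_jitter / rate
    onsets <- sort(pmax(onsets, 0))
    onsets <- onsets[onsets < dur]
  }
  durations <- diff(c(onsets, dur))
  k <- assign_swaras(durations, spec$swara_weights)
  octave <- sample(c(-1L, 0L, 1L), length(onsets), replace = TRUE,
                   prob = spec$octave_weights)
  swara <- ALL_CENTS[k]
  cents <- 1200 * octave + swara + unname(spec$cent_offsets[k])
  data.frame(onset_s = onsets, duration_s = durations, swara = swara,
             octave = octave, cents = cents,
             freq_hz = spec$tonic_hz * 2^(cents / 1200))
}

# Frame-wise ground-truth pitch track for a generated melody.
melody_pitch_track <- function(melody, spec, duration_s, hop_s = 0.03) {
  t <- seq(hop_s / 2, duration_s, by = hop_s)
  i <- findInterval(t, melody$onset_s)
  voiced <- i >= 1L
  cents <- rep(NA_real_, length(t))
  cents[voiced] <- melody$cents[i[voiced]]
  hz <- rep(NA_real_, length(t))
  hz[voiced] <- melody$freq_hz[i[voiced]]
  new_pitch_track(time_s = t, hz = hz, voiced = voiced,
                  tonic_hz = spec$tonic_hz)
}

# Additive synthesis: harmonic drone + enveloped harmonic melody notes +
# optional percussive clicks on the beat grid.
synthesize_audio <- function(melody, spec, mode, sample_rate = 22050) {
  n <- round(mode$duration_s * sample_rate)
  t <- seq_len(n) / sample_rate
  wave <- numeric(n)
  if (spec$drone_amp > 0) {
    drone_h <- c(1, 0.4, 0.2)
    for (h in seq_along(drone_h))
      wave <- wave + spec$drone_amp * drone_h[h] *
        sin(2 * pi * spec$tonic_hz * h * t)
  }
  harm <- c(1, 0.5, 0.3, 0.2)
  for (r in seq_len(nrow(melody))) {
    i0 <- floor(melody$onset_s[r] * sample_rate) + 1L
    i1 <- min(n, floor((melody$onset_s[r] + melody$duration_s[r]) * sample_rate))
    if (i1 < i0) next
    m <- i1 - i0 + 1L
    tt <- seq_len(m) / sample_rate
    attack <- pmin(1, tt / 0.02)
    release <- pmin(1, (m - seq_len(m) + 1) / (0.02 * sample_rate))
    env <- attack * release * exp(-tt / max(0.4, 0.6 * melody$duration_s[r]))
    tone <- numeric(m)
    f <- melody$freq_hz[r]
    for (h in seq_along(harm))
      tone <- tone + harm[h] * sin(2 * pi * f * h * tt)
    wave[i0:i1] <- wave[i0:i1] + env * tone
  }
  if (isTRUE(mode$pulse_track)) {
    beats <- seq(0, mode$duration_s - 1e-9, by = 1 / mode$event_rate)
    burst_n <- round(0.03 * sample_rate)
    decay <- exp(-seq_len(burst_n) / (0.006 * sample_rate))
    for (b in beats) {
      i0 <- floor(b * sample_rate) + 1L
      i1 <- min(n, i0 + burst_n - 1L)
      if (i1 < i0) next
      m <- i1 - i0 + 1L
      wave[i0:i1] <- wave[i0:i1] + 1.2 * runif(m, -1, 1) * decay[seq_len(m)]
    }
  }
  peak <- max(abs(wave))
  if (peak > 0) wave <- wave / peak * 0.9
  wave
}

#' Render a synthetic raga excerpt with ground truth
#'
#' Synthesizes a mono excerpt (continuous tonic drone plus a melody of
#' discrete notes drawn from the raga's swara weights; in gat mode also a
#' percussive click layer) and returns the waveform together with the
#' ground-truth pitch track and note list. Byte-identical output for
#' identical arguments and seed.
#'
#' @param spec a [raga_spec()].
#' @param mode a [mode_spec()].
#' @param seed integer seed; every random draw derives from it.
#' @param sample_rate audio sampling rate in Hz (default 22050).
#' @param render_audio if `FALSE`, skip waveform synthesis and return only
#'   the ground-truth melody and pitch track (fast path for tonality work).
#' @return object of class `raga_audio`: list with `wave` (or `NULL`),
#'   `sample_rate`, `pitch_track`, `melody`, `spec`, `mode`.
#' @export
generate_raga_audio <- function(spec, mode, seed, sample_rate = 22050,
                                render_audio = TRUE) {
  stopifnot(inherits(spec, "raga_spec"), inherits(mode, "mode_spec"))
  if (mode$duration_s <= 0) stop("zero-duration excerpt requested")
  with_seed(seed, {
    melody <- generate_melody(spec, mode)
    track <- melody_pitch_track(melody, spec, mode$duration_s)
    wave <- if (render_audio)
      synthesize_audio(melody, spec, mode, sample_rate) else NULL
    structure(list(wave = wave, sample_rate = sample_rate,
                   pitch_track = track, melody = melody,
                   spec = spec, mode = mode),
              class = "raga_audio")
  })
}

#' The default stimulus set: 12 synthetic ragas spanning the tonality range
#'
#' Twelve raga specifications whose prescribed m/M tonality ratios span
#' near 0 to 1.4, mirroring a stimulus design in which ragas are ordered by
#' increasing tonal ratio. Each raga uses a 5-7 swara subset; minor mass is
#' spread over its komal swaras and major mass over its shuddh swaras so
#' that the implied ratio equals the target exactly.
#'
#' @return named list of 12 [raga_spec()] objects.
#' @export
default_raga_set <- function() {
  targets <- c(0, 0.06, 0.12, 0.2, 0.3, 0.42, 0.56, 0.72, 0.88, 1.05,
               1.22, 1.4)
  major_sets <- list(
    c(0, 200, 400, 700, 900), c(0, 200, 500, 700, 1100),
    c(0, 400, 500, 700, 900), c(0, 200, 400, 700), c(0, 500, 700, 900),
    c(0, 200, 700, 1100), c(0, 400, 700), c(0, 500, 700),
    c(0, 200, 700), c(0, 700, 900), c(0, 500, 700), c(0, 700))
  minor_sets <- list(
    integer(0), c(300), c(100, 800), c(300, 1000), c(100, 600),
    c(300, 800), c(100, 300, 1000), c(100, 600, 800), c(300, 800, 1000),
    c(100, 300, 600), c(100, 300, 800, 1000), c(100, 300, 600, 800, 1000))
  specs <- vector("list", 12L)
  for (i in seq_len(12L)) {
    w <- setNames(numeric(12L), as.character(ALL_CENTS))
    p_minor <- targets[i] / (1 + targets[i])
    if (length(minor_sets[[i]]))
      w[as.character(minor_sets[[i]])] <- p_minor / length(minor_sets[[i]])
    w[as.character(major_sets[[i]])] <- (1 - p_minor) / length(major_sets[[i]])
    specs[[i]] <- raga_spec(sprintf("raga%02d", i), w)
  }
  setNames(specs, vapply(specs, `[[`, "", "name"))
}
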