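# Rhythm descriptors: spectral-flux onset strength, pulse clarity from the
# entropy of the onset-envelope fluctuation spectrum, and note-onset event
# density.

# Short-time Fourier magnitude spectrogram (Hann window), chunked to bound
# memory on long excerpts.
stft_mag <- function(wave, win = 1024L, hop = 256L) {
  if (length(wave) < win) wave <- c(wave, numeric(win - length(wave)))
  starts <- seq(1L, length(wave) - win + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  nb <- win %/% 2L
  out <- matrix(0, nrow = nb, ncol = length(starts))
  chunk <- 2048L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    cols <- c0:min(length(starts), c0 + chunk - 1L)
    idx <- outer(0:(win - 1L), starts[cols], `+`)
    M <- matrix(wave[idx] * hann, nrow = win)
    Fm <- mvfft(M)
    out[, cols] <- Mod(Fm[seq_len(nb), , drop = FALSE])
  }
  out
}

#' Spectral-flux onset-strength envelope
#'
#' Half-wave rectified frame-to-frame increase in short-time spectral
#' magnitude, summed over frequency: a sampled envelope that rises at note
#' and percussion onsets.
#'
#' @param wave mono waveform.
#' @param sample_rate sampling rate in Hz.
#' @param win,hop STFT window and hop in samples.
#' @return list with `strength` (one value per frame), `rate` (envelope
#'   sampling rate in Hz) and `times` (frame times in seconds).
#' @export
onset_strength <- function(wave, sample_rate, win = 1024L, hop = 256L) {
  stopifnot(is.numeric(wave), is_scalar_number(sample_rate), sample_rate > 0)
  S <- stft_mag(wave, win, hop)
  flux <- c(0, colSums(pmax(S[, -1L, drop = FALSE] -
                              S[, -ncol(S), drop = FALSE], 0)))
  list(strength = flux, rate = sample_rate / hop,
       times = (seq_along(flux) - 1L) * hop / sample_rate)
}

#' Normalized Shannon entropy of a power distribution
#'
#' `H / log(n)` for the distribution obtained by normalizing `power` to
#' sum 1: 0 when all mass sits in one bin, 1 when the distribution is
#' perfectly flat.
#'
#' @param power non-negative power values (at least 2 bins).
#' @return normalized entropy in \[0, 1\].
#' @export
normalized_entropy <- function(power) {
  stopifnot(is.numeric(power), length(power) >= 2L, all(power >= 0))
  tot <- sum(power)
  if (tot <= 0) return(1)  # no structure at all: maximally uninformative
  p <- power / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(power))
}

#' Pulse clarity of an excerpt
#'
#' How clearly a regular beat is perceptible, operationalized as one minus
#' the normalized Shannon entropy of the fluctuation spectrum of the
#' onset-strength envelope: music with a distinct, regular fluctuation
#' spectrum (an easily perceived beat) concentrates envelope power at the
#' beat rate and its harmonics and so scores high; rhythmically free
#' material has a flat fluctuation spectrum and scores low. Absolute values
#' depend on this operationalization; only orderings and contrasts are
#' asserted against published descriptions.
#'
#' @param wave mono waveform of at least 5 seconds.
#' @param sample_rate sampling rate in Hz.
#' @param band fluctuation band in Hz considered rhythmic (default
#'   0.25-10).
#' @param envelope optional precomputed [onset_strength()] result (the
#'   waveform is then ignored).
#' @return pulse clarity in \[0, 1\].
#' @export
pulse_clarity <- function(wave = NULL, sample_rate = NULL,
                          band = c(0.25, 10), envelope = NULL) {
  if (is.null(envelope)) {
    stopifnot(is.numeric(wave), is_scalar_number(sample_rate))
    if (length(wave) / sample_rate < 5)
      stop("pulse clarity needs at least 5 s of audio")
    envelope <- onset_strength(wave, sample_rate)
  }
  e <- envelope$strength - mean(envelope$strength)
  n <- length(e)
  if (n < 8L) stop("envelope too short for a fluctuation spectrum")
  spec <- Mod(fft(e))[2:(n %/% 2L)]^2
  freqs <- (1:(n %/% 2L - 1L)) * envelope$rate / n
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stop("fluctuation band is empty at this envelope length")
  1 - normalized_entropy(spec[sel])
}

#' Detect note onsets by peak-picking the spectral flux
#'
#' Local maxima of the onset-strength envelope exceeding
#' `median + threshold * sd`, separated by at least `min_gap_s`.
#'
#' @param wave mono waveform.
#' @param sample_rate sampling rate in Hz.
#' @param threshold peak threshold in envelope standard deviations above
#'   the median (fixed default 1.5).
#' @param min_gap_s minimum spacing between reported onsets in seconds.
#' @param envelope optional precomputed [onset_strength()] result.
#' @return onset times in seconds (possibly empty).
#' @export
detect_onsets <- function(wave = NULL, sample_rate = NULL, threshold = 1.5,
                          min_gap_s = 0.12, envelope = NULL) {
  if (is.null(envelope)) {
    stopifnot(is.numeric(wave), is_scalar_number(sample_rate))
    envelope <- onset_strength(wave, sample_rate)
  }
  s <- envelope$strength
  n <- length(s)
  if (n < 3L || sd(s) == 0) return(numeric(0))
  # light smoothing to merge double peaks
  sm <- stats::filter(s, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  thr <- median(sm) + threshold * sd(sm)
  is_peak <- sm > thr &
    sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1L], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(numeric(0))
  min_gap <- min_gap_s * envelope$rate
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    } else if (sm[i] > sm[keep[length(keep)]]) {
      keep[length(keep)] <- i  # same burst, keep the stronger peak
      last <- i
    }
  }
  envelope$times[keep]
}

#' Event density: note onsets per second
#'
#' A tempo proxy. Either supply onset times directly, or see
#' [event_density_audio()] to detect them from audio first.
#'
#' @param onsets numeric vector of onset times (or any vector whose length
#'   is the onset count).
#' @param duration_s excerpt duration in seconds, > 0.
#' @return onsets per second.
#' @export
event_density <- function(onsets, duration_s) {
  stopifnot(is_scalar_number(duration_s))
  if (duration_s <= 0) stop("duration_s must be positive")
  length(onsets) / duration_s
}

#' Event density estimated from audio
#'
#' @param wave mono waveform.
#' @param sample_rate sampling rate in Hz.
#' @param ... passed to [detect_onsets()].
#' @return detected onsets per second.
#' @export
event_density_audio <- function(wave, sample_rate, ...) {
  event_density(detect_onsets(wave, sample_rate, ...),
                length(wave) / sample_rate)
}

#' Paired comparison of a rhythm descriptor across presentation modes
#'
#' Paired t-test of per-raga feature values between matched alaap and gat
#' renditions (df = n - 1). The sign convention is alaap minus gat, so a
#' descriptor that is higher in gat yields a negative statistic.
#'
#' @param values_alaap,values_gat equal-length per-raga feature vectors.
#' @return list with `statistic`, `df`, `p.value`, and `mean_diff`
#'   (alaap - gat).
#' @export
paired_mode_test <- function(values_alaap, values_gat) {
  stopifnot(is.numeric(values_alaap), is.numeric(values_gat),
            length(values_alaap) == length(values_gat))
  if (length(values_alaap) < 2L)
    stop("need at least 2 paired observations")
  d <- values_alaap - values_gat
  n <- length(d)
  if (sd(d) == 0) {
    # degenerate pairing: all differences identical
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(statistic = t_stat, df = n - 1,
                p.value = if (mean(d) == 0) 1 else 0, mean_diff = mean(d)))
  }
  tt <- t.test(values_alaap, values_gat, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_diff = unname(tt$estimate))
}
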