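# Pitch representation: cents relative to a tonic, frame-wise pitch tracks,
# and a simple autocorrelation pitch estimator for real audio.

#' Convert a frequency to cents relative to a tonic
#'
#' `1200 * log2(f1 / f0)`: the tonic interval in cents between a note at
#' `f1` Hz and the tonic at `f0` Hz.
#'
#' @param f1 note frequency in Hz (vectorized).
#' @param f0 tonic frequency in Hz.
#' @return interval(s) in cents.
#' @export
hz_to_cents <- function(f1, f0) {
  if (any(!is.finite(f1)) || any(!is.finite(f0)) ||
      any(f1 <= 0) || any(f0 <= 0))
    stop("frequencies must be positive and finite")
  1200 * log2(f1 / f0)
}

#' Convert cents relative to a tonic back to Hz
#' @param cents interval(s) in cents.
#' @param f0 tonic frequency in Hz.
#' @return frequency in Hz.
#' @export
cents_to_hz <- function(cents, f0) {
  stopifnot(all(is.finite(cents)), all(f0 > 0))
  f0 * 2^(cents / 1200)
}

# Constructor shared by the generator and the estimator.
new_pitch_track <- function(time_s, hz, voiced, tonic_hz) {
  cents <- rep(NA_real_, length(time_s))
  ok <- voiced & is.finite(hz) & hz > 0
  cents[ok] <- hz_to_cents(hz[ok], tonic_hz)
  structure(
    data.frame(time_s = time_s, hz = hz, cents = cents, voiced = voiced),
    tonic_hz = tonic_hz,
    class = c("pitch_track", "data.frame"))
}

#' Assemble a pitch track from times and frequencies
#'
#' @param time_s frame times in seconds.
#' @param hz melodic pitch per frame in Hz (`NA` where unvoiced).
#' @param tonic_hz tonic reference frequency in Hz.
#' @param voiced logical voicing flags; defaults to finite positive `hz`.
#' @return a `pitch_track` data frame (`time_s`, `hz`, `cents`, `voiced`)
#'   with the tonic stored as an attribute.
#' @export
pitch_track <- function(time_s, hz, tonic_hz,
                        voiced = is.finite(hz) & hz > 0) {
  stopifnot(is.numeric(time_s), is.numeric(hz),
            length(time_s) == length(hz), length(voiced) == length(hz),
            is_scalar_number(tonic_hz), tonic_hz > 0)
  if (any(voiced & (!is.finite(hz) | hz <= 0)))
    stop("voiced frames must have positive pitch")
  new_pitch_track(time_s, hz, voiced, tonic_hz)
}

#' Estimate a melodic pitch track from audio by autocorrelation
#'
#' Frame-wise predominant-pitch estimation: each 40 ms frame is
#' autocorrelated via FFT, the normalized autocorrelation peak is searched
#' within the plausible melodic range, and the lag is refined by parabolic
#' interpolation. Frames whose peak clarity or energy falls below threshold
#' are flagged unvoiced; silence yields an all-unvoiced track (not an
#' error). With a strong tonic drone the estimator may lock to the drone;
#' ground-truth tracks from the generator are the preferred input for
#' tonality work.
#'
#' @param wave mono waveform in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param tonic_hz tonic reference frequency in Hz.
#' @param hop_s frame hop in seconds (default 0.03, i.e. one estimate per
#'   30 ms).
#' @param fmin,fmax melodic search range in Hz.
#' @param clarity_min minimum normalized autocorrelation peak for a frame
#'   to count as voiced.
#' @return a `pitch_track`.
#' @export
estimate_pitch_track <- function(wave, sample_rate, tonic_hz, hop_s = 0.03,
                                 fmin = 80, fmax = 1000,
                                 clarity_min = 0.5) {
  stopifnot(is.numeric(wave), is_scalar_number(sample_rate),
            sample_rate > 0, is_scalar_number(tonic_hz), tonic_hz > 0)
  win <- 2L^as.integer(ceiling(log2(0.04 * sample_rate)))
  hop <- max(1L, round(hop_s * sample_rate))
  if (length(wave) < win)
    wave <- c(wave, numeric(win - length(wave)))
  starts <- seq(1L, length(wave) - win + 1L, by = hop)
  nfr <- length(starts)
  nfft <- 2L * win
  lag_min <- max(2L, floor(sample_rate / fmax))
  lag_max <- min(win - 2L, ceiling(sample_rate / fmin))
  global_rms <- sqrt(mean(wave^2))
  hz <- rep(NA_real_, nfr)
  clarity <- numeric(nfr)
  rms <- numeric(nfr)
  chunk <- 512L
  for (c0 in seq(1L, nfr, by = chunk)) {
    cols <- c0:min(nfr, c0 + chunk - 1L)
    idx <- outer(0:(win - 1L), starts[cols], `+`)
    M <- matrix(wave[idx], nrow = win)
    M <- sweep(M, 2L, colMeans(M))
    rms[cols] <- sqrt(colMeans(M^2))
    Fm <- mvfft(rbind(M, matrix(0, win, ncol(M))))
    R <- Re(mvfft(Mod(Fm)^2, inverse = TRUE)) / nfft
    r0 <- R[1L, ]
    r0[r0 <= 0] <- Inf  # silent frame: normalized acf -> 0
    Rn <- sweep(R[seq_len(lag_max + 2L), , drop = FALSE], 2L, r0, `/`)
    seg <- Rn[(lag_min + 1L):(lag_max + 1L), , drop = FALSE]
    pk <- max.col(t(seg), ties.method = "first")
    for (j in seq_along(cols)) {
      lag <- lag_min + pk[j] - 1L
      cl <- seg[pk[j], j]
      clarity[cols[j]] <- cl
      if (!is.finite(cl) || cl < clarity_min) next
      # parabolic refinement around the integer lag
      ym <- Rn[lag, j]; y0 <- Rn[lag + 1L, j]; yp <- Rn[lag + 2L, j]
      den <- ym - 2 * y0 + yp
      delta <- if (is.finite(den) && abs(den) > 1e-12)
        0.5 * (ym - yp) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      hz[cols[j]] <- sample_rate / (lag + delta)
    }
  }
  voiced <- is.finite(hz) & rms > 1e-5 & rms > 0.02 * global_rms
  hz[!voiced] <- NA_real_
  new_pitch_track(time_s = (starts - 1L) / sample_rate + win / (2 * sample_rate),
                  hz = hz, voiced = voiced, tonic_hz = tonic_hz)
}

#' Write a pitch track to CSV
#'
#' Columns `time_s`, `hz`, `cents`, `voiced`; the tonic is recorded in a
#' comment-free side channel (first row of a `tonic_hz` column).
#'
#' @param track a `pitch_track`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pitch_track <- function(track, path) {
  stopifnot(inherits(track, "pitch_track"))
  df <- as.data.frame(track)
  df$tonic_hz <- attr(track, "tonic_hz")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pitch track from CSV
#'
#' @param path CSV path written by [write_pitch_track()], or any CSV with
#'   `time_s` plus `hz` or `cents` columns.
#' @param tonic_hz tonic in Hz; defaults to the file's `tonic_hz` column.
#' @return a `pitch_track`.
#' @export
read_pitch_track <- function(path, tonic_hz = NULL) {
  df <- read.csv(path)
  if (is.null(tonic_hz)) {
    if (!"tonic_hz" %in% names(df))
      stop("tonic_hz not given and not recorded in ", path)
    tonic_hz <- df$tonic_hz[1L]
  }
  if (!"hz" %in% names(df)) {
    if (!"cents" %in% names(df))
      stop("pitch track CSV needs an 'hz' or 'cents' column")
    hz <- rep(NA_real_, nrow(df))
    ok <- is.finite(df$cents)
    hz[ok] <- cents_to_hz(df$cents[ok], tonic_hz)
    df$hz <- hz
  }
  voiced <- if ("voiced" %in% names(df)) as.logical(df$voiced)
            else is.finite(df$hz) & df$hz > 0
  new_pitch_track(df$time_s, df$hz, voiced, tonic_hz)
}
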