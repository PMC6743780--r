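# Per-excerpt feature extraction: tonality ratio, pulse clarity, event
# density.

#' Extract the three stimulus descriptors from a rendered excerpt
#'
#' Computes the tonality ratio (from the ground-truth pitch track or from
#' audio via [estimate_pitch_track()]), pulse clarity and event density for
#' one `raga_audio` excerpt. Rhythm descriptors need the waveform; when the
#' excerpt was generated with `render_audio = FALSE`, event density falls
#' back to the ground-truth onset count and pulse clarity is `NA`.
#'
#' @param audio a `raga_audio` from [generate_raga_audio()].
#' @param pitch `"ground_truth"` (default) or `"estimated"`.
#' @return one-row [tibble::tibble()] with columns `raga`, `mode`,
#'   `tonality_ratio`, `pulse_clarity`, `event_density`.
#' @export
extract_features <- function(audio, pitch = c("ground_truth", "estimated")) {
  stopifnot(inherits(audio, "raga_audio"))
  pitch <- match.arg(pitch)
  track <- if (pitch == "ground_truth") {
    audio$pitch_track
  } else {
    if (is.null(audio$wave))
      stop("estimated pitch requested but the excerpt has no waveform")
    estimate_pitch_track(audio$wave, audio$sample_rate,
                         audio$spec$tonic_hz)
  }
  ton <- as.numeric(tonality_ratio(track))
  dur <- audio$mode$duration_s
  if (!is.null(audio$wave)) {
    env <- onset_strength(audio$wave, audio$sample_rate)
    pc <- pulse_clarity(envelope = env)
    ed <- event_density(detect_onsets(envelope = env), dur)
  } else {
    pc <- NA_real_
    ed <- event_density(audio$melody$onset_s, dur)
  }
  tibble::tibble(raga = audio$spec$name, mode = audio$mode$mode,
                 tonality_ratio = ton, pulse_clarity = pc,
                 event_density = ed)
}
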