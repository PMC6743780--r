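# Tonic-interval histogram over three octaves, octave folding, and the
# minor/major tonality ratio.

#' Tonic-interval histogram of a pitch track
#'
#' Each voiced frame is expressed in cents relative to the tonic and
#' assigned to the nearest 100-cent bin labeled -1200 to 2400 (three
#' octaves around the central one). Frames outside \[-1250, 2450) are
#' dropped and counted.
#'
#' @param track a `pitch_track` with at least one voiced frame.
#' @return object of class `interval_histogram`: `counts` (named, 37
#'   bins), `total_voiced`, `n_dropped`.
#' @export
interval_histogram <- function(track) {
  stopifnot(inherits(track, "pitch_track"))
  v <- track$cents[track$voiced & is.finite(track$cents)]
  if (length(v) == 0L)
    stop("pitch track has no voiced frames")
  bin <- 100 * round(v / 100)
  labels <- seq(-1200, 2400, by = 100)
  in_range <- bin >= -1200 & bin <= 2400
  counts <- table(factor(bin[in_range], levels = labels))
  structure(
    list(counts = setNames(as.integer(counts), names(counts)),
         total_voiced = length(v),
         n_dropped = sum(!in_range)),
    class = "interval_histogram")
}

#' Fold a three-octave interval histogram into one octave
#'
#' Bins sharing a pitch class (labels congruent modulo 1200 cents) are
#' summed, so e.g. the komal re (minor second) class collects the -1100,
#' 100 and 1300 cent bins. Total counts are conserved.
#'
#' @param hist an [interval_histogram()].
#' @return object of class `swara_profile`: `counts` and `proportions`
#'   over the 12 pitch classes (0 to 1100 cents), `tonality_ratio`, and a
#'   `tonality_undefined` flag (zero major-class mass).
#' @export
fold_octaves <- function(hist) {
  stopifnot(inherits(hist, "interval_histogram"))
  labels <- as.integer(names(hist$counts))
  pc <- labels %% 1200L
  folded <- vapply(ALL_CENTS,
                   function(k) sum(hist$counts[pc == k]), numeric(1))
  folded <- setNames(folded, as.character(ALL_CENTS))
  total <- sum(folded)
  props <- if (total > 0) folded / total else folded
  m <- sum(props[as.character(MINOR_CENTS)])
  M <- sum(props[as.character(MAJOR_CENTS)])
  undefined <- M <= 0
  structure(
    list(counts = folded, proportions = props,
         tonality_ratio = if (undefined) Inf else m / M,
         tonality_undefined = undefined),
    class = "swara_profile")
}

#' Minor-to-major tonality ratio of a folded swara profile
#'
#' Summed occupancy of the five minor (komal) pitch classes 100, 300, 600,
#' 800, 1000 cents divided by summed occupancy of the seven major (shuddh)
#' classes 0, 200, 400, 500, 700, 900, 1100 cents. The ratio is invariant
#' to uniform rescaling of the counts. Zero major-class mass gives an
#' undefined (infinite) ratio, flagged via the `"undefined"` attribute.
#'
#' @param x a `swara_profile` (from [fold_octaves()]), an
#'   `interval_histogram`, a `pitch_track`, or a length-12 vector of
#'   pitch-class occupancies.
#' @return the m/M ratio, with attribute `undefined` (logical).
#' @export
tonality_ratio <- function(x) {
  if (inherits(x, "pitch_track")) x <- interval_histogram(x)
  if (inherits(x, "interval_histogram")) x <- fold_octaves(x)
  if (inherits(x, "swara_profile"))
    return(structure(x$tonality_ratio, undefined = x$tonality_undefined))
  stopifnot(is.numeric(x), length(x) == 12L, all(x >= 0))
  x <- setNames(as.numeric(x), as.character(ALL_CENTS))
  m <- sum(x[as.character(MINOR_CENTS)])
  M <- sum(x[as.character(MAJOR_CENTS)])
  if (M <= 0) return(structure(Inf, undefined = TRUE))
  structure(m / M, undefined = FALSE)
}

#' @export
print.swara_profile <- function(x, ...) {
  cat("Folded swara profile (12 pitch classes, cents above tonic)\n")
  print(round(x$proportions, 4))
  if (x$tonality_undefined) {
    cat("tonality ratio m/M: undefined (no major-class mass)\n")
  } else {
    cat(sprintf("tonality ratio m/M: %.4f\n", x$tonality_ratio))
  }
  invisible(x)
}

#' @export
plot.swara_profile <- function(x, ...) {
  graphics::barplot(x$proportions, xlab = "pitch class (cents above tonic)",
                    ylab = "occupancy proportion", ...)
  invisible(x)
}
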