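# Minimal RIFF PCM WAV reader/writer (16-bit, mono).

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1\] and quantized to 16 bits.
#'
#' @param samples numeric vector of samples in \[-1, 1\].
#' @param sample_rate sampling rate in Hz.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is_scalar_number(sample_rate), sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")   # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readChar(con, 4L, useBytes = TRUE), "RIFF"))
    stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, integer(), size = 2, endian = "little"),
        channels = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16L) readBin(con, raw(), n = sz - 16L)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      readBin(con, raw(), n = sz)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples))
    stop("malformed WAV file: ", path)
  if (fmt$format != 1L || fmt$bits != 16L || fmt$channels != 1L)
    stop("only 16-bit PCM mono WAV is supported")
  list(samples = pmax(-1, samples / 32767), sample_rate = fmt$sample_rate)
}
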