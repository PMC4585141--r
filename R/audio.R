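#' Audio signal container
#'
#' The unit all DSP in this package operates on: a mono sampled waveform
#' with its sample rate and optional provenance metadata.
#'
#' @param samples Numeric vector of samples (any real scale; WAV export
#'   clips to \[-1, 1\]).
#' @param sample_rate Sampling rate in Hz.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate, meta = list()) {
  if (!is.numeric(samples)) abort("`samples` must be numeric.")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    abort("`sample_rate` must be a single positive number.")
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate),
         meta = meta),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

as_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.double(x)
}

#' Read a RIFF WAV file (PCM 16-bit mono)
#'
#' Minimal chunk-walking reader for the only format the package writes.
#'
#' @param path Path to a `.wav` file.
#' @return An `audio_signal` with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2L, size = 2L, endian = "little")
      channels <- fmt[2L]
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (fmt[1L] != 1L || bits != 16L)
        abort("Only PCM 16-bit WAV is supported.")
      extra <- sz - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz / 2L, size = 2L, signed = TRUE,
                         endian = "little")
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples) || is.null(sample_rate))
    abort("Malformed WAV: missing fmt or data chunk.")
  if (channels != 1L) abort("Only mono WAV is supported.")
  audio_signal(samples / 32768, sample_rate, meta = list(path = path))
}

#' Write an audio signal as RIFF WAV (PCM 16-bit mono)
#'
#' @param x An `audio_signal` (samples clipped to \[-1, 1\]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "audio_signal"))
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(v, size) writeBin(as.integer(v), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(36L + 2L * n, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16L, 4L)
  w_int(1L, 2L); w_int(1L, 2L)                      # PCM, mono
  w_int(round(x$sample_rate), 4L)
  w_int(round(x$sample_rate) * 2L, 4L)              # byte rate
  w_int(2L, 2L); w_int(16L, 2L)                     # block align, bits
  writeChar("data", con, eos = NULL); w_int(2L * n, 4L)
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
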