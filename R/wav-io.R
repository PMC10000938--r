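# Minimal RIFF/WAVE I/O: 16-bit PCM, mono. Cry recordings in this domain are
# plain 44.1 kHz/16-bit mono captures, so only that subset is supported.

#' Write a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit signed integers
#' with `round(x * 32767)`.
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  assert_scalar_num(rate, "rate", lo = 1)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return a list with `samples` (amplitudes in `[-1, 1]`, dequantized by
#'   `pcm / 32767`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV is supported", call. = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size %/% 2L, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
  }
  if (is.null(rate) || is.null(samples))
    stop("malformed WAV file (missing fmt or data chunk): ", path, call. = FALSE)
  if (channels != 1L) stop("only mono WAV is supported", call. = FALSE)
  if (bits != 16L) stop("only 16-bit WAV is supported", call. = FALSE)
  list(samples = samples / 32767, rate = rate)
}
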