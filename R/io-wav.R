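#' Write a waveform as 16-bit PCM mono WAV
#'
#' @param w An [rt_wave]; samples outside \[-1, 1\] are clipped.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "rt_wave"))
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  rate <- as.integer(round(w$rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(c(1L, 1L), con, size = 2, endian = "little")     # PCM, mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")     # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")    # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF reader covering the files this package writes: linear PCM,
#' one channel, 16 bits per sample. Chunks other than \code{fmt } and
#' \code{data} are skipped.
#'
#' @param path Path to the WAV file.
#' @return An [rt_wave] with samples in \[-1, 1\].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("corrupted WAV (no data chunk): ", path, call. = FALSE)
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      rest <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L || rest[2] != 16L)
        stop("unsupported WAV encoding (need 16-bit PCM mono): ", path,
             call. = FALSE)
      if (sz > 16L) invisible(readBin(con, raw(), sz - 16L))
    } else if (id == "data") {
      if (is.null(rate))
        stop("corrupted WAV (data before fmt): ", path, call. = FALSE)
      pcm <- readBin(con, integer(), sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      if (length(pcm) < sz / 2L)
        stop("corrupted WAV (truncated data): ", path, call. = FALSE)
      return(rt_wave(pcm / 32767, rate))
    } else {
      invisible(readBin(con, raw(), sz + sz %% 2L))
    }
  }
}
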