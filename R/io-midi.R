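# variable-length quantity encoding used by Standard MIDI Files
vlq_encode <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

u32be <- function(x) as.raw(c(x %/% 16777216L %% 256L, x %/% 65536L %% 256L,
                              x %/% 256L %% 256L, x %% 256L))
u16be <- function(x) as.raw(c(x %/% 256L %% 256L, x %% 256L))

#' Write tap times as a Standard MIDI File
#'
#' Minimal type-0 SMF: one track with a fixed tempo (120 bpm, 480 ticks per
#' quarter, i.e. 960 ticks per second) and one note-on/note-off pair per
#' tap.
#'
#' @param tap_times_s Numeric tap times in seconds (sorted internally).
#' @param path Output path.
#' @param pitch MIDI note number (default 60).
#' @param velocity Note-on velocity (default 100).
#' @return \code{path}, invisibly.
#' @export
write_midi_taps <- function(tap_times_s, path, pitch = 60L,
                            velocity = 100L) {
  ppq <- 480L
  tempo <- 500000L                       # microseconds per quarter note
  ticks_per_s <- ppq * 1e6 / tempo       # 960
  on_ticks <- as.integer(round(sort(tap_times_s) * ticks_per_s))
  ev_ticks <- integer(0); ev_bytes <- list()
  for (tk in on_ticks) {
    ev_ticks <- c(ev_ticks, tk, tk + 24L)
    ev_bytes <- c(ev_bytes,
                  list(as.raw(c(0x90L, pitch, velocity)),
                       as.raw(c(0x80L, pitch, 0L))))
  }
  o <- order(ev_ticks)
  ev_ticks <- ev_ticks[o]; ev_bytes <- ev_bytes[o]
  track <- c(vlq_encode(0L), as.raw(c(0xFF, 0x51, 0x03)),
             as.raw(c(tempo %/% 65536L, tempo %/% 256L %% 256L,
                      tempo %% 256L)))
  prev <- 0L
  for (i in seq_along(ev_ticks)) {
    track <- c(track, vlq_encode(ev_ticks[i] - prev), ev_bytes[[i]])
    prev <- ev_ticks[i]
  }
  track <- c(track, vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MThd", con, eos = NULL)
  writeBin(u32be(6L), con)
  writeBin(c(u16be(0L), u16be(1L), u16be(ppq)), con)
  writeChar("MTrk", con, eos = NULL)
  writeBin(u32be(length(track)), con)
  writeBin(track, con)
  invisible(path)
}

#' Read note-on times from a Standard MIDI File
#'
#' Parses a type-0/1 SMF and returns the onset times (seconds) of all
#' note-on events with nonzero velocity, using the first tempo meta event
#' found (default 120 bpm). Running status is supported.
#'
#' @param path Path to the MIDI file.
#' @return Sorted numeric vector of note onset times in seconds.
#' @export
read_midi_taps <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  if (length(raw) < 14L || rawToChar(raw[1:4]) != "MThd")
    stop("not a Standard MIDI File: ", path, call. = FALSE)
  ppq <- as.integer(raw[13]) * 256L + as.integer(raw[14])
  if (ppq >= 32768L)
    stop("SMPTE time division is not supported", call. = FALSE)
  pos <- 15L
  tempo <- 500000
  onsets_ticks <- numeric(0)
  while (pos + 8L <= length(raw)) {
    if (rawToChar(raw[pos:(pos + 3L)]) != "MTrk") break
    tlen <- sum(as.integer(raw[(pos + 4L):(pos + 7L)]) * c(16777216, 65536,
                                                           256, 1))
    p <- pos + 8L
    end <- p + tlen
    tick <- 0
    status <- NULL
    while (p < end) {
      # delta time (VLQ)
      dt <- 0
      repeat {
        b <- as.integer(raw[p]); p <- p + 1L
        dt <- dt * 128 + b %% 128L
        if (b < 128L) break
      }
      tick <- tick + dt
      b <- as.integer(raw[p])
      if (b >= 128L) { status <- b; p <- p + 1L }
      if (is.null(status)) stop("corrupted MIDI track", call. = FALSE)
      if (status == 255L) {                       # meta event
        type <- as.integer(raw[p]); p <- p + 1L
        len <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          len <- len * 128 + bb %% 128L
          if (bb < 128L) break
        }
        if (type == 81L && len == 3L) {
          tempo <- sum(as.integer(raw[p:(p + 2L)]) * c(65536, 256, 1))
        }
        p <- p + len
        status <- NULL                            # meta clears running status
      } else if (status %in% c(240L, 247L)) {     # sysex
        len <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          len <- len * 128 + bb %% 128L
          if (bb < 128L) break
        }
        p <- p + len
        status <- NULL
      } else {
        hi <- status %/% 16L
        n_data <- if (hi %in% c(12L, 13L)) 1L else 2L
        data <- as.integer(raw[p:(p + n_data - 1L)])
        p <- p + n_data
        if (hi == 9L && data[2] > 0L)
          onsets_ticks <- c(onsets_ticks, tick)
      }
    }
    pos <- end
  }
  sort(onsets_ticks * tempo / ppq / 1e6)
}
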