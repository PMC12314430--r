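#' Mono waveform container
#'
#' A minimal container for sampled mono audio: a numeric vector of samples
#' (nominally in \[-1, 1\]) plus a sampling rate. Sample \code{i} (1-based)
#' sits at time \code{(i - 1) / rate_hz} seconds.
#'
#' @param samples Numeric vector of finite samples.
#' @param rate_hz Sampling rate in Hz (positive scalar).
#' @return An object of class \code{rt_wave}: a list with elements
#'   \code{samples} and \code{rate_hz}.
#' @examples
#' w <- rt_wave(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration(w)
#' @export
rt_wave <- function(samples, rate_hz) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("`rate_hz` must be a positive scalar", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz)),
            class = "rt_wave")
}

#' @export
print.rt_wave <- function(x, ...) {
  cat(sprintf("<rt_wave: %d samples @ %g Hz, %.3f s>\n",
              length(x$samples), x$rate_hz, duration(x)))
  invisible(x)
}

#' Waveform duration in seconds
#' @param w An \code{rt_wave}.
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "rt_wave"))
  length(w$samples) / w$rate_hz
}

#' Energy / ZCR contour on a 1-ms frame grid
#'
#' Frame series with a fixed 1-ms hop. Frame \code{k} (1-based) is centred at
#' \code{t0_s + (k - 1) * 0.001} seconds. \code{kind} records the processing
#' stage: \code{"raw"} (windowed mean squared amplitude), \code{"smoothed"},
#' \code{"difference"} (adjacent-frame energy change, may be negative), or
#' \code{"zcr"} (zero-crossing rate per ms).
#'
#' @param values Numeric frame values.
#' @param t0_s Time of the first frame centre (seconds).
#' @param kind One of \code{"raw"}, \code{"smoothed"}, \code{"difference"},
#'   \code{"zcr"}.
#' @return An object of class \code{rt_contour}.
#' @export
rt_contour <- function(values, t0_s = 0,
                       kind = c("raw", "smoothed", "difference", "zcr")) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  if (kind %in% c("raw", "smoothed") && any(values < -1e-12))
    stop("energy contour values must be nonnegative", call. = FALSE)
  structure(list(values = as.numeric(values), t0_s = as.numeric(t0_s),
                 hop_s = 0.001, kind = kind),
            class = "rt_contour")
}

#' @export
print.rt_contour <- function(x, ...) {
  cat(sprintf("<rt_contour[%s]: %d frames, t0 = %g s, hop = 1 ms>\n",
              x$kind, length(x$values), x$t0_s))
  invisible(x)
}

#' Frame centre times of a contour
#' @param e An \code{rt_contour}.
#' @return Numeric vector of frame-centre times in seconds.
#' @export
frame_times <- function(e) {
  stopifnot(inherits(e, "rt_contour"))
  e$t0_s + (seq_along(e$values) - 1L) * e$hop_s
}

# 1-based frame indices whose centres fall in [start, end)
frames_in_interval <- function(e, start_s, end_s) {
  t <- frame_times(e)
  which(t >= start_s - 1e-12 & t < end_s - 1e-12)
}

# index of the frame centre nearest to time t (clamped to the domain)
nearest_frame <- function(e, t_s) {
  k <- round((t_s - e$t0_s) / e$hop_s) + 1
  pmin(pmax(as.integer(k), 1L), length(e$values))
}
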