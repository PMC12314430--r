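#' Raw energy contour
#'
#' Squares the raw amplitudes and averages them in a sliding window (default
#' 40 ms) advanced in 1-ms steps, yielding one frame per millisecond. Frame
#' centres start at t = 0; windows that overhang the signal edges are
#' truncated to the available samples.
#'
#' @param w An [rt_wave].
#' @param window_s Analysis window length in seconds (default 0.040).
#' @return An [rt_contour] of kind \code{"raw"} (nonnegative).
#' @export
raw_energy <- function(w, window_s = 0.040) {
  stopifnot(inherits(w, "rt_wave"))
  if (duration(w) < window_s)
    stop(sprintf("waveform shorter than the %g-ms analysis window",
                 window_s * 1000), call. = FALSE)
  win <- window_bounds(w, window_s)
  cs <- c(0, cumsum(w$samples^2))
  vals <- (cs[win$hi + 1L] - cs[win$lo]) / (win$hi - win$lo + 1L)
  rt_contour(pmax(vals, 0), t0_s = 0, kind = "raw")
}

# shared frame grid: centres at k ms, k = 0 .. floor(last sample time / 1 ms);
# returns 1-based sample index bounds of the (truncated) window per frame
window_bounds <- function(w, window_s) {
  n <- length(w$samples)
  rate <- w$rate_hz
  n_frames <- floor((n - 1) / rate * 1000) + 1L
  centers <- (seq_len(n_frames) - 1L) / 1000
  half <- window_s / 2
  lo <- pmax(1L, as.integer(ceiling((centers - half) * rate - 1e-9)) + 1L)
  hi <- pmin(n, as.integer(floor((centers + half) * rate + 1e-9)) + 1L)
  list(lo = lo, hi = hi, centers = centers)
}

#' Zero-crossing rate per frame
#'
#' Counts strict sign changes (products of adjacent samples < 0) inside the
#' same sliding window used by [raw_energy] and expresses the count per
#' millisecond, on the identical 1-ms frame grid.
#'
#' @inheritParams raw_energy
#' @return An [rt_contour] of kind \code{"zcr"}, in crossings per ms. A pure
#'   sinusoid of frequency f gives about 2f crossings per second, i.e.
#'   2f/1000 per ms.
#' @export
zero_crossing_rate <- function(w, window_s = 0.040) {
  stopifnot(inherits(w, "rt_wave"))
  if (duration(w) < window_s)
    stop(sprintf("waveform shorter than the %g-ms analysis window",
                 window_s * 1000), call. = FALSE)
  win <- window_bounds(w, window_s)
  x <- w$samples
  cross <- as.numeric(x[-length(x)] * x[-1] < 0)  # crossing between i, i+1
  cs <- c(0, cumsum(cross))
  # crossings attributed to sample pairs fully inside the window
  n_cross <- cs[pmax(win$hi, win$lo)] - cs[win$lo]
  dur_ms <- (win$hi - win$lo + 1L) / w$rate_hz * 1000
  rt_contour(n_cross / dur_ms, t0_s = 0, kind = "zcr")
}

#' Attenuate fricative frames of a raw energy contour
#'
#' Frames whose zero-crossing rate strictly exceeds \code{threshold}
#' crossings/ms are multiplied by \code{factor} (default: reduced to a
#' quarter); all other frames are untouched. Applied to the raw contour,
#' before smoothing.
#'
#' @param e Raw energy contour ([rt_contour], kind \code{"raw"}).
#' @param zcr Zero-crossing-rate contour on the identical frame grid.
#' @param threshold ZCR threshold in crossings per ms (default 7.5).
#' @param factor Multiplicative reduction for supra-threshold frames
#'   (default 0.25).
#' @return The attenuated raw contour.
#' @export
attenuate_fricatives <- function(e, zcr, threshold = 7.5, factor = 0.25) {
  stopifnot(inherits(e, "rt_contour"), inherits(zcr, "rt_contour"))
  if (length(e$values) != length(zcr$values) ||
      abs(e$t0_s - zcr$t0_s) > 1e-12)
    stop("energy and ZCR contours are on different frame grids", call. = FALSE)
  out <- e$values
  hit <- zcr$values > threshold
  out[hit] <- out[hit] * factor
  rt_contour(out, t0_s = e$t0_s, kind = e$kind)
}

#' Zero-phase moving-average smoothing
#'
#' An order-N moving average applied zero-phase: a causal N-frame average is
#' run forward and (on the time-reversed series) backward, and the two passes
#' are averaged. The combined impulse response is symmetric over 2N - 1
#' frames, so landmark times are not delayed; affine segments pass through
#' unchanged in the interior. Edge windows are truncated. Output length
#' equals input length.
#'
#' @param e An [rt_contour].
#' @param order Window length in frames (>= 1).
#' @return Smoothed contour; energy kinds are marked \code{"smoothed"}.
#' @export
smooth_contour <- function(e, order) {
  stopifnot(inherits(e, "rt_contour"))
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order))
    stop("`order` must be a positive integer", call. = FALSE)
  order <- as.integer(order)
  f <- causal_ma(e$values, order)
  b <- rev(causal_ma(rev(e$values), order))
  out <- (f + b) / 2
  kind <- if (e$kind %in% c("raw", "smoothed")) "smoothed" else e$kind
  if (kind == "smoothed") out <- pmax(out, 0)
  rt_contour(out, t0_s = e$t0_s, kind = kind)
}

# causal moving average over `order` frames, left-truncated at the start
causal_ma <- function(x, order) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  k <- seq_len(n)
  lo <- pmax(k - order + 1L, 1L)
  (cs[k + 1L] - cs[lo]) / (k - lo + 1L)
}

#' Smoothed energy-difference contour
#'
#' First difference of the smoothed energy contour (frame k minus frame
#' k - 1, first frame set to 0), smoothed again with a moving average
#' (default order 10). Values may be negative; positive values mark energy
#' rises and the per-syllable maximum of this contour is the maxD landmark.
#'
#' @param e Smoothed energy contour.
#' @param order Moving-average order for the post-difference smoothing
#'   (default 10).
#' @return An [rt_contour] of kind \code{"difference"}.
#' @export
energy_difference <- function(e, order = 10) {
  stopifnot(inherits(e, "rt_contour"))
  if (e$kind != "smoothed")
    stop("`e` must be a smoothed energy contour", call. = FALSE)
  d <- c(0, diff(e$values))
  smooth_contour(rt_contour(d, t0_s = e$t0_s, kind = "difference"), order)
}

#' Full smoothed-energy chain for one waveform
#'
#' Convenience wrapper running the canonical pre-processing chain: raw
#' windowed energy, fricative attenuation (ZCR > threshold reduced to a
#' quarter), order-6 smoothing, adjacent-frame differencing, order-10
#' smoothing of the difference.
#'
#' @inheritParams raw_energy
#' @param smooth_order Moving-average order for the energy contour (default 6).
#' @param diff_order Moving-average order for the difference contour
#'   (default 10).
#' @param zcr_threshold,zcr_factor Passed to [attenuate_fricatives].
#' @return List with elements \code{raw}, \code{zcr}, \code{smoothed},
#'   \code{difference}, all [rt_contour]s on the same grid.
#' @export
energy_chain <- function(w, window_s = 0.040, smooth_order = 6,
                         diff_order = 10, zcr_threshold = 7.5,
                         zcr_factor = 0.25) {
  raw <- raw_energy(w, window_s)
  zcr <- zero_crossing_rate(w, window_s)
  att <- attenuate_fricatives(raw, zcr, zcr_threshold, zcr_factor)
  sm <- smooth_contour(att, smooth_order)
  d <- energy_difference(sm, diff_order)
  list(raw = raw, zcr = zcr, smoothed = sm, difference = d)
}

#' Locate maxD within a syllable
#'
#' maxD -- the operational P-centre approximation -- is the highest value of
#' the smoothed energy-difference contour among frames whose centres lie in
#' the half-open syllable interval \[start, end). Ties go to the earliest
#' frame.
#'
#' @param d Smoothed energy-difference contour ([rt_contour], kind
#'   \code{"difference"}).
#' @param syll Numeric length-2 vector \code{c(start_s, end_s)}.
#' @return List with \code{time_s} and \code{value}.
#' @export
find_maxD <- function(d, syll) {
  stopifnot(inherits(d, "rt_contour"))
  if (d$kind != "difference")
    stop("`d` must be an energy-difference contour", call. = FALSE)
  idx <- frames_in_interval(d, syll[1], syll[2])
  if (length(idx) == 0L)
    stop("syllable interval does not overlap the contour domain",
         call. = FALSE)
  v <- d$values[idx]
  k <- idx[which.max(v)]  # which.max returns the first maximum
  list(time_s = frame_times(d)[k], value = d$values[k])
}

#' maxD landmarks for a table of syllables
#'
#' @param d Smoothed energy-difference contour.
#' @param syllables Data frame with columns \code{start_s}, \code{end_s} and
#'   (optionally) identifying columns, one row per syllable.
#' @return The identifying columns plus \code{maxd_s} and \code{maxd_value}.
#' @export
maxd_landmarks <- function(d, syllables) {
  stopifnot(is.data.frame(syllables),
            all(c("start_s", "end_s") %in% names(syllables)))
  res <- lapply(seq_len(nrow(syllables)), function(i) {
    find_maxD(d, c(syllables$start_s[i], syllables$end_s[i]))
  })
  keep <- setdiff(names(syllables), c("start_s", "end_s"))
  out <- syllables[, keep, drop = FALSE]
  out$maxd_s <- vapply(res, `[[`, numeric(1), "time_s")
  out$maxd_value <- vapply(res, `[[`, numeric(1), "value")
  out
}
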