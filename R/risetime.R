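#' Local energy maximum within a syllable
#'
#' Highest smoothed-energy frame whose centre lies in the half-open syllable
#' interval; ties -- including near-ties within a small relative tolerance,
#' which arise as numerical ripple on energy plateaus -- go to the earliest
#' frame. If the contour is still within tolerance of its maximum at the
#' last in-syllable frame (still rising at the syllable edge), the result is
#' flagged as degenerate.
#'
#' @param e Smoothed energy contour ([rt_contour]).
#' @param syll Numeric \code{c(start_s, end_s)}.
#' @param tie_tol Relative tolerance under which frames count as tied with
#'   the maximum (default 1e-4).
#' @return List with \code{time_s}, \code{value}, \code{degenerate}.
#' @export
local_energy_maximum <- function(e, syll, tie_tol = 1e-4) {
  stopifnot(inherits(e, "rt_contour"))
  idx <- frames_in_interval(e, syll[1], syll[2])
  if (length(idx) == 0L)
    stop("syllable interval does not overlap the contour domain",
         call. = FALSE)
  v <- e$values[idx]
  maxv <- max(v)
  k <- idx[which(v >= maxv - tie_tol * abs(maxv))[1]]
  list(time_s = frame_times(e)[k], value = e$values[k],
       degenerate = (v[length(v)] >= maxv - tie_tol * abs(maxv)))
}

#' Find the foot of an energy rise
#'
#' Walks backward from a local energy maximum in steps of \code{step_s}
#' (default 5 ms), computing the contour slope over each step. The rise foot
#' is the first boundary where the slope of the step further from the maximum
#' drops by more than \code{drop_frac} relative to the step nearer the
#' maximum (i.e. \code{slope_far < (1 - drop_frac) * slope_near}); a zero or
#' negative far-side slope qualifies immediately. The search is bounded below
#' by \code{lower_bound_s} (typically the previous syllable's energy maximum,
#' otherwise the contour start).
#'
#' If no boundary qualifies before the bound is reached, the minimum-energy
#' frame between the bound and the maximum is returned and flagged for
#' review; flagged feet are the cases a human annotator would correct by
#' hand, and can be overridden via [rise_measurement].
#'
#' @param e Smoothed energy contour.
#' @param t_max_s Time of the local energy maximum (seconds).
#' @param step_s Slope-evaluation step (default 0.005 s).
#' @param drop_frac Relative slope drop that marks the foot (default 0.70).
#' @param lower_bound_s Earliest time the search may reach (default: contour
#'   start).
#' @return List with \code{time_s}, \code{value}, \code{flagged}.
#' @export
find_preceding_minimum <- function(e, t_max_s, step_s = 0.005,
                                   drop_frac = 0.70, lower_bound_s = NULL) {
  stopifnot(inherits(e, "rt_contour"))
  t <- frame_times(e)
  if (t_max_s < t[1] - 1e-12 || t_max_s > t[length(t)] + 1e-12)
    stop("`t_max_s` lies outside the contour domain", call. = FALSE)
  if (is.null(lower_bound_s)) lower_bound_s <- t[1]
  lower_bound_s <- max(lower_bound_s, t[1])

  e_at <- function(tt) e$values[nearest_frame(e, tt)]
  slope_near <- NULL
  b_near <- t_max_s                      # boundary nearer the maximum
  repeat {
    b_far <- b_near - step_s
    if (b_far < lower_bound_s - 1e-12) break
    s_far <- (e_at(b_near) - e_at(b_far)) / step_s
    if (!is.null(slope_near)) {
      # a foot requires the step nearer the maximum to actually rise
      qualifies <- slope_near > 0 &&
        (s_far <= 0 || s_far < (1 - drop_frac) * slope_near)
      if (qualifies)
        return(list(time_s = b_near, value = e_at(b_near), flagged = FALSE))
    }
    slope_near <- s_far
    b_near <- b_far
  }
  # fallback: flattest/lowest point between the bound and the maximum
  idx <- which(t >= lower_bound_s - 1e-12 & t <= t_max_s + 1e-12)
  k <- idx[which.min(e$values[idx])]
  list(time_s = t[k], value = e$values[k], flagged = TRUE)
}

#' Rise-time and rise-slope of a syllable
#'
#' Combines the in-syllable energy maximum with the preceding-minimum search:
#' rise-time is the interval from the energy minimum to the maximum spanning
#' the syllable's maxD landmark, and rise-slope is the energy gain over that
#' interval divided by its duration. A manual override for the minimum
#' replaces the automatic search and marks the measurement as corrected.
#'
#' @param e Smoothed energy contour.
#' @param syll Numeric \code{c(start_s, end_s)}.
#' @param maxd maxD landmark for this syllable, as returned by [find_maxD].
#' @param override_min_s Optional manually corrected minimum time (seconds).
#' @param prev_max_s Optional time of the previous syllable's energy maximum,
#'   bounding the backward search.
#' @param step_s,drop_frac Passed to [find_preceding_minimum].
#' @return List with \code{t_min_s}, \code{e_min}, \code{t_max_s},
#'   \code{e_max}, \code{rise_time_s}, \code{rise_slope} (energy units per
#'   second), \code{corrected}, \code{flagged}. \code{flagged} is set when
#'   the minimum search fell back to the degenerate path or when maxD does
#'   not lie inside \[t_min, t_max\].
#' @export
rise_measurement <- function(e, syll, maxd, override_min_s = NULL,
                             prev_max_s = NULL, step_s = 0.005,
                             drop_frac = 0.70) {
  mx <- local_energy_maximum(e, syll)
  flagged <- FALSE
  if (!is.null(override_min_s)) {
    t_min <- override_min_s
    e_min <- e$values[nearest_frame(e, t_min)]
    corrected <- TRUE
  } else {
    mn <- find_preceding_minimum(e, mx$time_s, step_s = step_s,
                                 drop_frac = drop_frac,
                                 lower_bound_s = prev_max_s)
    t_min <- mn$time_s
    e_min <- mn$value
    flagged <- mn$flagged
    corrected <- FALSE
  }
  if (t_min >= mx$time_s)
    stop("rise minimum does not precede the maximum", call. = FALSE)
  if (maxd$time_s < t_min - 1e-9 || maxd$time_s > mx$time_s + 1e-9)
    flagged <- TRUE                    # rise does not span maxD: review
  rt <- mx$time_s - t_min
  list(t_min_s = t_min, e_min = e_min,
       t_max_s = mx$time_s, e_max = mx$value,
       rise_time_s = rt,
       rise_slope = max(mx$value - e_min, 0) / rt,
       corrected = corrected, flagged = flagged)
}

#' Rise measurements for a table of syllables
#'
#' Applies [rise_measurement] per syllable, bounding each backward search by
#' the previous syllable's energy maximum. Optional per-syllable overrides
#' (manual corrections) are matched by row index.
#'
#' @param e Smoothed energy contour.
#' @param d Smoothed energy-difference contour (for maxD).
#' @param syllables Data frame with \code{start_s}, \code{end_s} (plus id
#'   columns, preserved).
#' @param overrides Optional numeric vector of override minima, NA where the
#'   automatic search should run (length = number of syllables).
#' @return Data frame: id columns plus \code{t_min_s}, \code{e_min},
#'   \code{t_max_s}, \code{e_max}, \code{rise_time_s}, \code{rise_slope},
#'   \code{maxd_s}, \code{maxd_value}, \code{corrected}, \code{flagged}.
#' @export
rise_table <- function(e, d, syllables, overrides = NULL) {
  stopifnot(is.data.frame(syllables))
  n <- nrow(syllables)
  if (!is.null(overrides) && length(overrides) != n)
    stop("`overrides` must have one entry per syllable", call. = FALSE)
  prev_max <- NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    syll <- c(syllables$start_s[i], syllables$end_s[i])
    maxd <- find_maxD(d, syll)
    ov <- if (!is.null(overrides) && !is.na(overrides[i])) overrides[i]
    m <- rise_measurement(e, syll, maxd, override_min_s = ov,
                          prev_max_s = prev_max)
    prev_max <- m$t_max_s
    rows[[i]] <- data.frame(m[c("t_min_s", "e_min", "t_max_s", "e_max",
                                "rise_time_s", "rise_slope")],
                            maxd_s = maxd$time_s, maxd_value = maxd$value,
                            corrected = m$corrected, flagged = m$flagged)
  }
  keep <- setdiff(names(syllables), c("start_s", "end_s"))
  cbind(syllables[, keep, drop = FALSE], do.call(rbind, rows))
}

#' Hilbert-envelope rise measurement (alternative backend)
#'
#' Computes the analytic-signal magnitude of the waveform, low-pass filters
#' it with a ripple-free Gaussian frequency response, resamples it onto the
#' 1-ms frame grid, and applies the same maximum/preceding-minimum logic as
#' the smoothed-energy backend. The default scale (50 Hz, the upper edge of
#' the amplitude-envelope band) removes carrier ripple for any speech-like
#' f0 while keeping onset ramps sharp enough that a linear ramp's duration
#' is recovered to about 10 ms; heavier smoothing (e.g. 10 Hz) distorts
#' ramp durations and is available via the parameter. Provided for
#' cross-method comparison; the envelope is an amplitude (not an energy),
#' so slopes are in amplitude units per second.
#'
#' @param w An [rt_wave].
#' @param syll Numeric \code{c(start_s, end_s)}.
#' @param cutoff_hz Gaussian low-pass scale in Hz (frequency-domain SD of
#'   the response, default 50).
#' @param prev_max_s Optional backward-search bound (seconds).
#' @return As [rise_measurement], plus \code{envelope} (the [rt_contour]
#'   actually searched) as an attribute.
#' @export
hilbert_rise <- function(w, syll, cutoff_hz = 50, prev_max_s = NULL) {
  env <- hilbert_envelope(w, cutoff_hz)
  mx <- local_energy_maximum(env, syll)
  vals <- env$values[frames_in_interval(env, syll[1], syll[2])]
  flat <- (max(vals) - min(vals)) < 0.05 * max(vals)
  mn <- find_preceding_minimum(env, mx$time_s, lower_bound_s = prev_max_s)
  flagged <- mn$flagged
  if (flat || mn$time_s >= mx$time_s) {
    # flat envelope: no usable rise; report a degenerate, flagged record
    out <- list(t_min_s = mn$time_s, e_min = mn$value, t_max_s = mx$time_s,
                e_max = mx$value, rise_time_s = NA_real_,
                rise_slope = NA_real_, corrected = FALSE, flagged = TRUE)
  } else {
    rt <- mx$time_s - mn$time_s
    out <- list(t_min_s = mn$time_s, e_min = mn$value, t_max_s = mx$time_s,
                e_max = mx$value, rise_time_s = rt,
                rise_slope = max(mx$value - mn$value, 0) / rt,
                corrected = FALSE, flagged = flagged)
  }
  attr(out, "envelope") <- env
  out
}

#' Low-passed Hilbert amplitude envelope on the 1-ms grid
#'
#' @inheritParams hilbert_rise
#' @return An [rt_contour] of kind \code{"smoothed"} (amplitude units).
#' @export
hilbert_envelope <- function(w, cutoff_hz = 50) {
  stopifnot(inherits(w, "rt_wave"))
  x <- w$samples
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  env_s <- fft_lowpass(env, w$rate_hz, cutoff_hz)
  # resample to frame centres at k ms
  idx <- nearest_sample_index(n, w$rate_hz)
  rt_contour(pmax(env_s[idx], 0), t0_s = 0, kind = "smoothed")
}

nearest_sample_index <- function(n, rate_hz) {
  n_frames <- floor((n - 1) / rate_hz * 1000) + 1L
  pmin(pmax(round((seq_len(n_frames) - 1L) / 1000 * rate_hz) + 1L, 1L), n)
}

# FFT low-pass with a Gaussian frequency response (SD = cutoff_hz).
# Monotone step response: no Gibbs ripple on envelope plateaus.
fft_lowpass <- function(x, rate_hz, cutoff_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * rate_hz
  f <- pmin(f, rate_hz - f)            # two-sided frequency axis
  g <- exp(-0.5 * (f / cutoff_hz)^2)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
}
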