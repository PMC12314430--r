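#' Subtract the recording latency from tap times
#'
#' @param tap_times Numeric vector of tap times in seconds.
#' @param latency_s Recording latency to subtract (default 0.005 s).
#' @return Corrected tap times; times that would become negative are clipped
#'   to 0 with a warning.
#' @export
correct_latency <- function(tap_times, latency_s = 0.005) {
  out <- tap_times - latency_s
  if (any(out < 0)) {
    warning(sum(out < 0), " tap(s) clipped to 0 after latency correction")
    out[out < 0] <- 0
  }
  out
}

#' Fold a looped tap train into cycle-relative times
#'
#' Assigns each tap to a repetition cycle and expresses it relative to that
#' cycle's onset. Taps up to \code{lead_s} (default 300 ms) before a cycle
#' onset count as anticipations of that cycle (negative relative time), so
#' the relative time lies in \[-lead_s, cycle_dur_s - lead_s). Taps in the
#' first \code{skip_reps} repetitions (participants start tapping from the
#' third repetition) and beyond repetition \code{n_reps} are discarded.
#'
#' @param tap_times Numeric tap times in seconds from the loop start.
#' @param cycle_dur_s Duration of one repetition cycle (seconds).
#' @param n_reps Number of repetitions in the loop.
#' @param skip_reps Leading repetitions to discard (default 2).
#' @param lead_s Anticipation window before a cycle onset (default 0.300 s).
#' @return Data frame with \code{cycle} (1-based repetition index) and
#'   \code{rel_time_s}.
#' @export
fold_cycles <- function(tap_times, cycle_dur_s, n_reps, skip_reps = 2,
                        lead_s = 0.300) {
  if (cycle_dur_s <= lead_s)
    stop("`cycle_dur_s` must exceed `lead_s`", call. = FALSE)
  cyc <- floor((tap_times + lead_s) / cycle_dur_s + 1e-12) + 1L
  rel <- tap_times - (cyc - 1L) * cycle_dur_s
  keep <- cyc > skip_reps & cyc <= n_reps
  data.frame(cycle = as.integer(cyc[keep]), rel_time_s = rel[keep])
}

#' Gaussian kernel density of cycle-relative tap times
#'
#' Kernel density estimate with 1/8 (by default) of the normal-reference
#' bandwidth 1.06 min(sd, IQR/1.34) n^(-1/5), evaluated on a uniform 1-ms
#' grid extended \code{cut} bandwidths beyond the data range. The IQR uses
#' linear-interpolation quantiles, so the full bandwidth equals
#' \code{stats::bw.nrd}. The density integrates to 1 over the grid (within
#' about 1 percent).
#'
#' @param rel_times Cycle-relative tap times (seconds); at least two
#'   distinct values.
#' @param grid_step_s Evaluation grid step (default 0.001 s).
#' @param bw_divisor Bandwidth divisor (default 8).
#' @param cut Grid extension beyond the data range, in bandwidths
#'   (default 4).
#' @return Object of class \code{rt_density}: list with \code{x} (grid),
#'   \code{y} (density), \code{bw} (bandwidth used), \code{bw_full}
#'   (undivided normal-reference bandwidth) and \code{n}.
#' @export
tap_density <- function(rel_times, grid_step_s = 0.001, bw_divisor = 8,
                        cut = 4) {
  rel_times <- as.numeric(rel_times)
  n <- length(rel_times)
  if (n < 2L || length(unique(rel_times)) < 2L)
    stop("degenerate distribution: need at least 2 distinct tap times",
         call. = FALSE)
  s <- stats::sd(rel_times)
  iqr <- unname(diff(stats::quantile(rel_times, c(0.25, 0.75), names = FALSE,
                                     type = 7)))
  bw_full <- 1.06 * min(s, iqr / 1.34) * n^(-1 / 5)
  if (!is.finite(bw_full) || bw_full <= 0)
    stop("degenerate distribution: zero bandwidth", call. = FALSE)
  h <- bw_full / bw_divisor
  lo <- floor((min(rel_times) - cut * h) / grid_step_s) * grid_step_s
  hi <- ceiling((max(rel_times) + cut * h) / grid_step_s) * grid_step_s
  x <- seq(lo, hi, by = grid_step_s)
  y <- numeric(length(x))
  for (chunk in split(rel_times, ceiling(seq_len(n) / 512))) {
    y <- y + colSums(stats::dnorm(outer(chunk, x, "-") / h))
  }
  y <- y / (n * h)
  structure(list(x = x, y = y, bw = h, bw_full = bw_full, n = n),
            class = "rt_density")
}

#' @export
print.rt_density <- function(x, ...) {
  cat(sprintf("<rt_density: n = %d taps, bw = %.4f s (full %.4f), grid %d>\n",
              x$n, x$bw, x$bw_full, length(x$x)))
  invisible(x)
}

#' Pick tapping peaks from a density estimate
#'
#' Local density maxima (strictly greater than both neighbours; plateaus are
#' represented by their centre frame) that reach at least
#' \code{rel_threshold} of the largest maximum. Peaks closer together than
#' \code{min_sep_s} are resolved by keeping the higher of the two, greedily
#' from the highest peak down (ties broken toward the earlier peak).
#'
#' @param d An \code{rt_density} (or any list with uniform \code{x} and
#'   \code{y}).
#' @param rel_threshold Minimum height relative to the global maximum
#'   (default 0.40).
#' @param min_sep_s Minimum separation between retained peaks
#'   (default 0.100 s).
#' @return Data frame with \code{time_s} and \code{density_value}, ordered
#'   by time; zero rows when no peak qualifies.
#' @export
find_tap_peaks <- function(d, rel_threshold = 0.40, min_sep_s = 0.100) {
  x <- d$x
  y <- d$y
  idx <- local_maxima_idx(y)
  if (length(idx) == 0L)
    return(data.frame(time_s = numeric(0), density_value = numeric(0)))
  keep <- y[idx] >= rel_threshold * max(y)
  idx <- idx[keep]
  # greedy from the highest peak down; earlier peak wins ties
  ord <- idx[order(-y[idx], x[idx])]
  chosen <- numeric(0)
  chosen_t <- numeric(0)
  for (k in ord) {
    if (all(abs(x[k] - chosen_t) >= min_sep_s - 1e-12)) {
      chosen <- c(chosen, k)
      chosen_t <- c(chosen_t, x[k])
    }
  }
  chosen <- sort(chosen)
  data.frame(time_s = x[chosen], density_value = y[chosen])
}

# indices of strict local maxima; plateaus contribute their centre frame
local_maxima_idx <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in seq_along(r$values)) {
    left_ok <- j > 1L && r$values[j - 1L] < r$values[j]
    right_ok <- j < length(r$values) && r$values[j + 1L] < r$values[j]
    if (left_ok && right_ok)
      out <- c(out, starts[j] + (r$lengths[j] - 1L) %/% 2L)
  }
  out
}
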