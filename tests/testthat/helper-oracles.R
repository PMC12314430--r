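# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# exhaustive argmax of contour values whose frame centres lie in [start, end)
oracle_argmax <- function(values, t0, start_s, end_s) {
  times <- t0 + (seq_along(values) - 1) * 0.001
  best_k <- NA_integer_
  best_v <- -Inf
  for (k in seq_along(values)) {
    if (times[k] >= start_s - 1e-12 && times[k] < end_s - 1e-12 &&
        values[k] > best_v) {
      best_v <- values[k]
      best_k <- k
    }
  }
  list(time_s = times[best_k], value = best_v)
}

# greedy-by-height peak selection, written as a plain double loop
oracle_peaks <- function(x, y, rel_threshold = 0.40, min_sep_s = 0.100) {
  cand <- integer(0)
  i <- 2L
  while (i <= length(y) - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < length(y) && y[j + 1L] == y[j]) j <- j + 1L
      if (j < length(y) && y[j + 1L] < y[j]) {
        cand <- c(cand, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cand <- cand[y[cand] >= rel_threshold * max(y)]
  kept <- integer(0)
  remaining <- cand[order(-y[cand], x[cand])]
  while (length(remaining) > 0L) {
    k <- remaining[1]
    kept <- c(kept, k)
    remaining <- remaining[abs(x[remaining] - x[k]) >= min_sep_s - 1e-12]
  }
  sort(kept)
}

# nearest-landmark assignment, one peak at a time, then nearest-peak per
# landmark; ties broken toward the earlier landmark / earlier peak
oracle_anchor <- function(peak_times, landmark_times, window_s = 0.120) {
  lt <- sort(landmark_times)
  assign <- data.frame(landmark = numeric(0), peak = numeric(0))
  for (p in sort(peak_times)) {
    best <- NULL
    for (l in lt) {
      d <- abs(p - l)
      if (d <= window_s + 1e-12 &&
          (is.null(best) || d < best$d - 1e-12)) best <- list(l = l, d = d)
    }
    if (!is.null(best))
      assign <- rbind(assign, data.frame(landmark = best$l, peak = p))
  }
  out <- data.frame(landmark = numeric(0), peak = numeric(0))
  for (l in unique(assign$landmark)) {
    sub <- assign[assign$landmark == l, ]
    sub <- sub[order(abs(sub$peak - l), sub$peak), ]
    out <- rbind(out, sub[1, ])
  }
  out[order(out$landmark), ]
}

# direct O(n * order) moving-average pair used to check smooth_contour
oracle_zero_phase_ma <- function(x, order) {
  n <- length(x)
  fwd <- numeric(n)
  bwd <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1L, k - order + 1L)
    fwd[k] <- mean(x[lo:k])
    hi <- min(n, k + order - 1L)
    bwd[k] <- mean(x[k:hi])
  }
  (fwd + bwd) / 2
}

# small padded ramp tone + its full energy chain (shared by several tests)
ramp_tone_chain <- function(ramp_s, pad_s = 0.15, dur_s = 0.6,
                            rate_hz = 44100) {
  w <- synth_tone(dur_s, 500, ramp_s, 0.05, 0.8, rate_hz)
  padded <- rt_wave(c(numeric(round(pad_s * rate_hz)), w$samples,
                      numeric(round(pad_s * rate_hz))), rate_hz)
  list(wave = padded, chain = energy_chain(padded),
       syll = c(pad_s, pad_s + dur_s))
}
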