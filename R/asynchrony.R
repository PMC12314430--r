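#' Anchor tapping peaks to maxD landmarks
#'
#' Each tapping peak is assigned to its nearest landmark provided the
#' distance is within the anchoring window (inclusive, default +/- 120 ms);
#' a peak equidistant from two landmarks goes to the earlier one. If several
#' peaks anchor to the same landmark, only the nearest peak is kept (ties:
#' the earlier peak). Signed asynchrony is peak time minus landmark time
#' (negative = anticipation); absolute asynchrony is its magnitude.
#'
#' @param peaks Data frame with \code{time_s} (e.g. from [find_tap_peaks]),
#'   or a numeric vector of peak times.
#' @param landmarks Data frame with \code{maxd_s} and an id column
#'   \code{syllable_idx} (plus optional \code{sentence_id}), or a numeric
#'   vector of landmark times.
#' @param window_ms Anchoring window half-width in ms (default 120).
#' @return Data frame with \code{syllable_idx}, \code{landmark_s},
#'   \code{peak_s}, \code{signed_ms}, \code{abs_ms}; zero rows if nothing
#'   anchors. Unmatched landmarks yield no record.
#' @export
anchor_peaks <- function(peaks, landmarks, window_ms = 120) {
  pt <- if (is.data.frame(peaks)) peaks$time_s else as.numeric(peaks)
  if (is.data.frame(landmarks)) {
    lt <- landmarks$maxd_s
    lid <- if ("syllable_idx" %in% names(landmarks))
      landmarks$syllable_idx else seq_along(lt)
  } else {
    lt <- as.numeric(landmarks)
    lid <- seq_along(lt)
  }
  empty <- data.frame(syllable_idx = integer(0), landmark_s = numeric(0),
                      peak_s = numeric(0), signed_ms = numeric(0),
                      abs_ms = numeric(0))
  if (length(pt) == 0L || length(lt) == 0L) return(empty)
  ord <- order(lt)
  lt <- lt[ord]; lid <- lid[ord]
  win <- window_ms / 1000
  # peak -> nearest landmark (ties to the earlier landmark)
  cand <- lapply(pt, function(p) {
    dd <- abs(p - lt)
    j <- which(dd <= min(dd) + 1e-12)[1]
    if (dd[j] <= win + 1e-12) c(j, p, dd[j]) else NULL
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # landmark attracts multiple peaks -> keep the nearest (earlier on ties)
  rows <- lapply(split(seq_len(nrow(cand)), cand[, 1]), function(ii) {
    sub <- cand[ii, , drop = FALSE]
    sub[order(sub[, 3], sub[, 2]), , drop = FALSE][1, ]
  })
  res <- do.call(rbind, rows)
  res <- res[order(res[, 1]), , drop = FALSE]
  j <- res[, 1]
  signed <- (res[, 2] - lt[j]) * 1000
  data.frame(syllable_idx = lid[j], landmark_s = lt[j], peak_s = res[, 2],
             signed_ms = signed, abs_ms = abs(signed), row.names = NULL)
}

#' Aggregate asynchronies by item (syllable)
#'
#' Per syllable, the median over participants of the signed and of the
#' absolute asynchronies (computed independently: the median of absolute
#' values is not the absolute value of the median). Even participant counts
#' use the midpoint of the two central order statistics.
#'
#' @param asynchronies Data frame with \code{syllable_idx} (optionally
#'   \code{sentence_id}), \code{signed_ms}, \code{abs_ms}, one row per
#'   participant-syllable record.
#' @return Data frame with one row per syllable: key columns,
#'   \code{median_signed_ms}, \code{median_abs_ms}, \code{n_participants}.
#' @export
aggregate_by_item <- function(asynchronies) {
  stopifnot(is.data.frame(asynchronies),
            all(c("syllable_idx", "signed_ms", "abs_ms") %in%
                  names(asynchronies)))
  keys <- intersect(c("sentence_id", "syllable_idx"), names(asynchronies))
  f <- interaction(asynchronies[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(asynchronies, f), function(g) {
    out <- g[1, keys, drop = FALSE]
    out$median_signed_ms <- stats::median(g$signed_ms)
    out$median_abs_ms <- stats::median(g$abs_ms)
    out$n_participants <- nrow(g)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[keys]), , drop = FALSE]
}
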