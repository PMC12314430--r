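#' Default sonority scale
#'
#' Sonority classes on a 0--9 scale anchored at voiceless stops (0) and open
#' vowels (9), following a conventional sonority hierarchy for the
#' intermediate classes. The intermediate values are a package default and
#' can be replaced by passing a custom table to [sonority_default].
#'
#' @return Named numeric vector of per-class sonority values.
#' @export
rt_sonority_table <- function() {
  c(voiceless_stop = 0, voiced_stop = 1, affricate = 1.5,
    voiceless_fricative = 2, voiced_fricative = 3, nasal = 4,
    lateral = 5, rhotic = 6, glide = 7, close_vowel = 8, open_vowel = 9)
}

#' Average phonological sonority of a syllable onset
#'
#' Mean per-segment sonority over the onset consonants; for onset-free
#' syllables the value reflects the sonority of the nucleus.
#'
#' @param onset_classes Character vector of onset segment classes (possibly
#'   empty), using the names of [rt_sonority_table].
#' @param nucleus_class Nucleus segment class, used when the onset is empty.
#' @param table Named sonority lookup (default [rt_sonority_table]).
#' @return Sonority value in \[0, 9\].
#' @examples
#' sonority_default(c("voiceless_stop", "lateral"))  # /pl/ -> 2.5
#' sonority_default(character(0), "open_vowel")      # onset-free -> 9
#' @export
sonority_default <- function(onset_classes = character(0),
                             nucleus_class = NULL,
                             table = rt_sonority_table()) {
  classes <- if (length(onset_classes) > 0L) onset_classes else nucleus_class
  if (is.null(classes) || length(classes) == 0L)
    stop("onset-free syllables need a `nucleus_class`", call. = FALSE)
  unknown <- setdiff(classes, names(table))
  if (length(unknown) > 0L)
    stop("unknown segment class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  mean(table[classes])
}

#' Intensity contour in dB on the 1-ms frame grid
#'
#' Mean power in a sliding window (default 32 ms), expressed as
#' 10 log10(power / ref). The reference corresponds to treating sample
#' values as sound pressure in Pa with the conventional 2e-5 Pa reference.
#'
#' @param w An [rt_wave].
#' @param window_s Window length in seconds (default 0.032).
#' @param ref_power Reference power (default (2e-5)^2).
#' @return An [rt_contour] of kind \code{"zcr"}-like dB values (plain frame
#'   series; silent frames are -Inf).
#' @keywords internal
intensity_db_contour <- function(w, window_s = 0.032, ref_power = 4e-10) {
  win <- window_bounds(w, window_s)
  cs <- c(0, cumsum(w$samples^2))
  p <- (cs[win$hi + 1L] - cs[win$lo]) / (win$hi - win$lo + 1L)
  rt_contour(10 * log10(pmax(p, 0) / ref_power), t0_s = 0, kind = "zcr")
}

#' Relative nucleus intensity
#'
#' Mean frame intensity (dB) over the syllable nucleus divided by the mean
#' frame intensity over the whole sentence, where sentence frames more than
#' \code{floor_db} below the sentence maximum (silences) are excluded from
#' the denominator. Dimensionless; about 1 for an average-loudness nucleus.
#'
#' @param w Sentence waveform ([rt_wave]).
#' @param nucleus Numeric \code{c(start_s, end_s)} of the nucleus.
#' @param sentence Optional \code{c(start_s, end_s)}; default: whole
#'   waveform.
#' @param window_s Intensity window (default 0.032 s).
#' @param floor_db Silence floor relative to the sentence maximum
#'   (default 60 dB).
#' @return List with \code{value} (NA when flagged) and \code{flagged}
#'   (TRUE when the nucleus is silent or the measurement is degenerate,
#'   mirroring syllables dropped for intensity-measurement failure).
#' @export
relative_intensity <- function(w, nucleus, sentence = NULL,
                               window_s = 0.032, floor_db = 60) {
  db <- intensity_db_contour(w, window_s)
  t <- frame_times(db)
  if (is.null(sentence)) sentence <- c(0, duration(w))
  sent_idx <- which(t >= sentence[1] - 1e-12 & t < sentence[2] - 1e-12)
  nuc_idx <- which(t >= nucleus[1] - 1e-12 & t < nucleus[2] - 1e-12)
  if (length(nuc_idx) == 0L || length(sent_idx) == 0L)
    return(list(value = NA_real_, flagged = TRUE))
  sv <- db$values[sent_idx]
  sv <- sv[is.finite(sv) & sv > max(sv[is.finite(sv)], -Inf) - floor_db]
  nv <- db$values[nuc_idx]
  if (length(sv) == 0L || !all(is.finite(nv)) || mean(sv) <= 0)
    return(list(value = NA_real_, flagged = TRUE))
  list(value = mean(nv) / mean(sv), flagged = FALSE)
}

#' Assemble the per-syllable analysis table
#'
#' Joins syllable annotations with rise measurements and maxD landmarks
#' (both keyed by \code{sentence_id} + \code{syllable_idx}), computes nucleus
#' duration and relative intensity, and applies the documented exclusion
#' rules: syllables with a three-consonant onset are dropped, as are
#' syllables whose intensity measurement failed. Onset complexity is recoded
#' as a categorical variable with levels 0/1/2 (reference 0) and metrical
#' weight as weak/strong (reference weak). Every exclusion is recorded in
#' the \code{"exclusions"} attribute.
#'
#' @param annotations Data frame: \code{sentence_id}, \code{syllable_idx},
#'   \code{start_s}, \code{end_s}, \code{nucleus_start_s},
#'   \code{nucleus_end_s}, \code{weight}, \code{onset_complexity},
#'   \code{sonority}.
#' @param rises Data frame from [rise_table] (keyed the same way), carrying
#'   \code{rise_time_s}, \code{rise_slope}, \code{maxd_s}, \code{corrected},
#'   \code{flagged}.
#' @param waveforms Named list of [rt_wave] keyed by \code{sentence_id}, or a
#'   single [rt_wave] when only one sentence is present.
#' @return Data frame, one row per retained syllable, with attribute
#'   \code{"exclusions"} (a data frame of dropped rows and reasons).
#' @export
build_feature_table <- function(annotations, rises, waveforms) {
  req <- c("sentence_id", "syllable_idx", "start_s", "end_s",
           "nucleus_start_s", "nucleus_end_s", "weight", "onset_complexity",
           "sonority")
  missing_cols <- setdiff(req, names(annotations))
  if (length(missing_cols) > 0L)
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- function(df) paste(df$sentence_id, df$syllable_idx, sep = "\r")
  if (anyDuplicated(key(annotations)) || anyDuplicated(key(rises)))
    stop("annotation/rise keys are not unique", call. = FALSE)
  orphan <- setdiff(key(annotations), key(rises))
  if (length(orphan) > 0L)
    stop("no rise measurement for syllable(s): ",
         paste(gsub("\r", ":", orphan), collapse = ", "), call. = FALSE)
  m <- match(key(annotations), key(rises))
  tab <- annotations
  for (col in c("rise_time_s", "rise_slope", "maxd_s", "maxd_value",
                "corrected", "flagged"))
    tab[[col]] <- rises[[col]][m]
  tab$nucleus_dur_s <- tab$nucleus_end_s - tab$nucleus_start_s

  if (inherits(waveforms, "rt_wave"))
    waveforms <- stats::setNames(list(waveforms), unique(tab$sentence_id)[1])
  tab$rel_intensity <- NA_real_
  int_fail <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    w <- waveforms[[as.character(tab$sentence_id[i])]]
    if (is.null(w))
      stop("no waveform for sentence ", tab$sentence_id[i], call. = FALSE)
    ri <- relative_intensity(w, c(tab$nucleus_start_s[i],
                                  tab$nucleus_end_s[i]))
    tab$rel_intensity[i] <- ri$value
    int_fail[i] <- ri$flagged
  }

  drop_onset <- tab$onset_complexity >= 3
  excl <- rbind(
    data.frame(sentence_id = tab$sentence_id[drop_onset],
               syllable_idx = tab$syllable_idx[drop_onset],
               reason = rep("onset_complexity_3", sum(drop_onset))),
    data.frame(sentence_id = tab$sentence_id[int_fail & !drop_onset],
               syllable_idx = tab$syllable_idx[int_fail & !drop_onset],
               reason = rep("intensity_measurement_failure",
                            sum(int_fail & !drop_onset))))
  tab <- tab[!drop_onset & !int_fail, , drop = FALSE]
  tab$onset_complexity <- factor(tab$onset_complexity,
                                 levels = c(0, 1, 2))
  tab$weight <- factor(tab$weight, levels = c("weak", "strong"))
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- excl
  tab
}
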