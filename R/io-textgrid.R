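#' Write syllable/nucleus annotations as a Praat TextGrid
#'
#' Emits a long-format TextGrid with two interval tiers, \code{"syllable"}
#' and \code{"nucleus"}. Labelled intervals carry \code{syl<k>} /
#' \code{nuc<k>}; gaps are empty-labelled.
#'
#' @param annotation Data frame with \code{syllable_idx}, \code{start_s},
#'   \code{end_s}, \code{nucleus_start_s}, \code{nucleus_end_s} (e.g. from
#'   [synth_sentence]).
#' @param path Output path.
#' @param xmax Total duration of the audio (default: last syllable end).
#' @return \code{path}, invisibly.
#' @export
write_textgrid <- function(annotation, path, xmax = NULL) {
  stopifnot(is.data.frame(annotation))
  if (is.null(xmax)) xmax <- max(annotation$end_s)
  syl <- tier_intervals(annotation$start_s, annotation$end_s,
                        sprintf("syl%d", annotation$syllable_idx), xmax)
  nuc <- tier_intervals(annotation$nucleus_start_s, annotation$nucleus_end_s,
                        sprintf("nuc%d", annotation$syllable_idx), xmax)
  fmt_num <- function(x) sprintf("%.10g", x)
  lines <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    "xmin = 0", paste0("xmax = ", fmt_num(xmax)),
    "tiers? <exists>", "size = 2", "item []:")
  for (tn in 1:2) {
    tier <- list(syl, nuc)[[tn]]
    name <- c("syllable", "nucleus")[tn]
    lines <- c(lines,
               sprintf("    item [%d]:", tn),
               '        class = "IntervalTier"',
               sprintf('        name = "%s"', name),
               "        xmin = 0",
               paste0("        xmax = ", fmt_num(xmax)),
               sprintf("        intervals: size = %d", nrow(tier)))
    for (i in seq_len(nrow(tier))) {
      lines <- c(lines,
                 sprintf("        intervals [%d]:", i),
                 paste0("            xmin = ", fmt_num(tier$xmin[i])),
                 paste0("            xmax = ", fmt_num(tier$xmax[i])),
                 sprintf('            text = "%s"', tier$text[i]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# fill gaps between labelled intervals with empty-text intervals
tier_intervals <- function(starts, ends, labels, xmax) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; labels <- labels[o]
  xmin <- numeric(0); xx <- numeric(0); txt <- character(0)
  cursor <- 0
  for (i in seq_along(starts)) {
    if (starts[i] > cursor + 1e-9) {
      xmin <- c(xmin, cursor); xx <- c(xx, starts[i]); txt <- c(txt, "")
    }
    xmin <- c(xmin, starts[i]); xx <- c(xx, ends[i]); txt <- c(txt, labels[i])
    cursor <- ends[i]
  }
  if (cursor < xmax - 1e-9) {
    xmin <- c(xmin, cursor); xx <- c(xx, xmax); txt <- c(txt, "")
  }
  data.frame(xmin = xmin, xmax = xx, text = txt)
}

#' Read interval tiers from a Praat TextGrid
#'
#' Parses long-format TextGrid files (as written by Praat or
#' [write_textgrid]) into a list of interval-tier data frames.
#'
#' @param path Path to the TextGrid.
#' @return Named list of data frames (\code{xmin}, \code{xmax},
#'   \code{text}), one per interval tier.
#' @export
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("ooTextFile", lines)) || !any(grepl("TextGrid", lines)))
    stop("not a TextGrid file: ", path, call. = FALSE)
  grab <- function(line, pat) {
    m <- regmatches(line, regexec(pat, line))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  tiers <- list()
  cur_name <- NULL
  cur <- NULL
  pending <- list(xmin = NA_real_, xmax = NA_real_)
  in_items <- FALSE
  for (ln in lines) {
    if (grepl("^\\s*item\\s*\\[\\d+\\]", ln)) {
      if (!is.null(cur_name)) tiers[[cur_name]] <- cur
      cur_name <- NULL
      cur <- data.frame(xmin = numeric(0), xmax = numeric(0),
                        text = character(0))
      in_items <- TRUE
      next
    }
    if (!in_items) next
    nm <- grab(ln, 'name\\s*=\\s*"([^"]*)"')
    if (!is.na(nm) && is.null(cur_name)) { cur_name <- nm; next }
    v <- grab(ln, "xmin\\s*=\\s*([-0-9.eE+]+)")
    if (!is.na(v) && grepl("^\\s{8,}", ln)) { pending$xmin <- as.numeric(v); next }
    v <- grab(ln, "xmax\\s*=\\s*([-0-9.eE+]+)")
    if (!is.na(v) && grepl("^\\s{8,}", ln)) { pending$xmax <- as.numeric(v); next }
    tx <- grab(ln, 'text\\s*=\\s*"([^"]*)"')
    if (!is.na(tx)) {
      cur <- rbind(cur, data.frame(xmin = pending$xmin,
                                   xmax = pending$xmax, text = tx))
      pending <- list(xmin = NA_real_, xmax = NA_real_)
    }
  }
  if (!is.null(cur_name)) tiers[[cur_name]] <- cur
  if (length(tiers) == 0L)
    stop("no interval tiers found in ", path, call. = FALSE)
  tiers
}

#' Extract the syllable table from TextGrid tiers
#'
#' Pairs the labelled intervals of the \code{"syllable"} and
#' \code{"nucleus"} tiers (matching \code{syl<k>} with \code{nuc<k>}) into
#' the annotation layout used across the package.
#'
#' @param tiers List from [read_textgrid].
#' @param sentence_id Sentence identifier for the output rows.
#' @return Data frame with \code{sentence_id}, \code{syllable_idx},
#'   \code{start_s}, \code{end_s}, \code{nucleus_start_s},
#'   \code{nucleus_end_s}.
#' @export
textgrid_syllables <- function(tiers, sentence_id = "s1") {
  if (!all(c("syllable", "nucleus") %in% names(tiers)))
    stop('TextGrid must contain tiers "syllable" and "nucleus"',
         call. = FALSE)
  syl <- tiers$syllable[tiers$syllable$text != "", , drop = FALSE]
  nuc <- tiers$nucleus[tiers$nucleus$text != "", , drop = FALSE]
  idx <- as.integer(sub("^syl", "", syl$text))
  nidx <- as.integer(sub("^nuc", "", nuc$text))
  m <- match(idx, nidx)
  if (anyNA(m))
    stop("nucleus tier missing interval(s) for syllable(s): ",
         paste(idx[is.na(m)], collapse = ", "), call. = FALSE)
  data.frame(sentence_id = sentence_id, syllable_idx = idx,
             start_s = syl$xmin, end_s = syl$xmax,
             nucleus_start_s = nuc$xmin[m], nucleus_end_s = nuc$xmax[m])
}
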