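# derive a deterministic child seed < 2^31 from (seed, k)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483629)
}

#' Pipeline run configuration
#'
#' Bundles every tunable constant of the analysis chain with its default:
#' the 40-ms energy window with 1-ms hop, moving-average orders 6 (energy)
#' and 10 (difference), the ZCR fricative threshold 7.5/ms with reduction
#' factor 0.25, the 5-ms slope step and 70 percent slope-drop rule for rise
#' feet, the 5-ms tap latency, 300-ms anticipation lead, 2 skipped
#' repetitions, kernel bandwidth divisor 8, 40 percent density threshold,
#' 100-ms peak separation, the +/-120-ms anchoring window, elimination
#' alpha 0.05 and correlation-matrix alpha 0.001 -- plus the synthetic-corpus
#' shape (sentences, syllables, participants, repetition count, tap jitter,
#' anticipation bias and miss rate).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Overrides for any default listed above (unknown names are an
#'   error).
#' @return A list of class \code{rt_config}.
#' @export
rt_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    # synthetic corpus shape
    n_sentences = 10L, syllables_per_sentence = 8L, n_participants = 12L,
    n_reps = 15L, gap_s = 0.08, cycle_pad_s = 0.40, rate_hz = 44100,
    jitter_sd_s = 0.020, bias_s = -0.030, miss_prob = 0.10,
    # acoustic chain
    window_s = 0.040, smooth_order = 6L, diff_order = 10L,
    zcr_threshold = 7.5, zcr_factor = 0.25,
    step_s = 0.005, drop_frac = 0.70,
    # tapping
    latency_s = 0.005, lead_s = 0.300, skip_reps = 2L,
    bw_divisor = 8, rel_threshold = 0.40, min_sep_s = 0.100,
    # asynchrony + models
    window_ms = 120, alpha = 0.05, corr_alpha = 0.001,
    corrections_csv = NULL)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(unlist(cfg[num & names(cfg) != "bias_s"]) < 0))
    stop("config parameters must be nonnegative", call. = FALSE)
  structure(cfg, class = "rt_config")
}

cfg_paths <- function(cfg) {
  list(audio = file.path(cfg$out_dir, "audio"),
       textgrids = file.path(cfg$out_dir, "textgrids"),
       taps = file.path(cfg$out_dir, "taps"),
       results = file.path(cfg$out_dir, "results"),
       features = file.path(cfg$out_dir, "features.csv"),
       loops = file.path(cfg$out_dir, "loops.csv"),
       truth = file.path(cfg$out_dir, "ground_truth.csv"))
}

sent_ids <- function(cfg) sprintf("s%02d", seq_len(cfg$n_sentences))

write_tab <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# random syllable specs for one sentence; one 3-consonant onset is planted
# in sentence 1 to exercise the exclusion rule
draw_specs <- function(cfg, sent_idx) {
  n <- cfg$syllables_per_sentence
  types <- c("none", "sonorant", "obstruent", "fricative")
  lapply(seq_len(n), function(j) {
    type <- sample(types, 1, prob = c(0.25, 0.3, 0.25, 0.2))
    cx <- if (sent_idx == 1L && j == 4L) 3L
          else sample(0:2, 1, prob = c(0.35, 0.45, 0.20))
    son <- if (cx == 0L) stats::runif(1, 7, 9) else stats::runif(1, 0, 7)
    wt <- sample(c("strong", "weak"), 1)
    # onset ramps lengthen with metrical weight and onset complexity, as in
    # natural speech, so the regression stage has real structure to recover
    ramp <- sample(c(0.015, 0.025, 0.04, 0.06), 1) *
      (1 + 0.4 * (wt == "strong") + 0.3 * min(cx, 2L))
    syllable_spec(
      onset_ramp_s = ramp, onset_type = type, weight = wt,
      nucleus_dur_s = stats::runif(1, 0.10, 0.25),
      peak_amp = stats::runif(1, 0.45, 0.9),
      decay_s = stats::runif(1, 0.04, 0.08),
      f0_hz = sample(c(180, 200, 220, 240), 1),
      onset_complexity = cx, sonority = son)
  })
}

#' Generate the synthetic corpus on disk
#'
#' Writes, per sentence, a WAV recording, a TextGrid with syllable and
#' nucleus tiers, and per participant a Standard MIDI File of simulated
#' taps; plus a linguistic feature sidecar CSV, loop metadata, and a
#' ground-truth CSV (true ramp landmarks and the anchor times the taps were
#' planted on). Tap anchors are the maxD landmarks measured on the
#' synthesized audio, offset by the configured anticipation bias with
#' Gaussian jitter and misses. Deterministic given \code{cfg$seed}.
#'
#' @param cfg An [rt_config].
#' @return Invisibly, the ground-truth data frame.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "rt_config"))
  p <- cfg_paths(cfg)
  for (d in c(cfg$out_dir, p$audio, p$textgrids, p$taps))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  feats <- list(); truth <- list(); loops <- list()
  for (i in seq_along(sent_ids(cfg))) {
    sid <- sent_ids(cfg)[i]
    specs <- with_seed(derive_seed(cfg$seed, i), draw_specs(cfg, i))
    syn <- synth_sentence(specs, gap_s = cfg$gap_s, rate_hz = cfg$rate_hz,
                          seed = derive_seed(cfg$seed, 1000L + i),
                          sentence_id = sid)
    write_wav(syn$wave, file.path(p$audio, paste0(sid, ".wav")))
    write_textgrid(syn$annotation,
                   file.path(p$textgrids, paste0(sid, ".TextGrid")),
                   xmax = duration(syn$wave))
    feats[[i]] <- syn$annotation[, c("sentence_id", "syllable_idx",
                                     "weight", "onset_complexity",
                                     "sonority")]
    # anchors: maxD measured on the synthesized audio
    chain <- energy_chain(syn$wave, cfg$window_s, cfg$smooth_order,
                          cfg$diff_order, cfg$zcr_threshold, cfg$zcr_factor)
    lm <- maxd_landmarks(chain$difference,
                         syn$annotation[, c("sentence_id", "syllable_idx",
                                            "start_s", "end_s")])
    cycle_dur <- duration(syn$wave) + cfg$cycle_pad_s
    loops[[i]] <- data.frame(sentence_id = sid, cycle_dur_s = cycle_dur,
                             n_reps = cfg$n_reps)
    spec <- tap_sim_spec(lm$maxd_s, cycle_dur, cfg$n_reps,
                         n_participants = cfg$n_participants,
                         jitter_sd_s = cfg$jitter_sd_s, bias_s = cfg$bias_s,
                         miss_prob = cfg$miss_prob,
                         seed = derive_seed(cfg$seed, 2000L + i))
    trains <- synth_taps(spec)
    for (pp in names(trains))
      write_midi_taps(trains[[pp]] + cfg$latency_s,  # emulate device latency
                      file.path(p$taps, sprintf("%s_%s.mid", sid, pp)))
    tr <- syn$annotation
    tr$anchor_s <- lm$maxd_s
    truth[[i]] <- tr
  }
  write_tab(do.call(rbind, feats), p$features)
  write_tab(do.call(rbind, loops), p$loops)
  truth <- do.call(rbind, truth)
  write_tab(truth, p$truth)
  invisible(truth)
}

#' Run the acoustic stage over a corpus on disk
#'
#' For each sentence: reads the WAV and TextGrid, runs the smoothed-energy
#' chain, locates maxD per syllable, measures rise-time and rise-slope
#' (honouring an optional manual-correction CSV with columns
#' \code{sentence_id}, \code{syllable_idx}, \code{override_min_s}), and
#' assembles the feature table with the documented exclusions. Writes
#' \code{landmarks.csv}, \code{rises.csv}, \code{feature_table.csv} and
#' \code{exclusions.csv} under \code{<out_dir>/results}.
#'
#' @param cfg An [rt_config].
#' @return Invisibly, the feature table.
#' @export
run_acoustics <- function(cfg) {
  stopifnot(inherits(cfg, "rt_config"))
  p <- cfg_paths(cfg)
  dir.create(p$results, recursive = TRUE, showWarnings = FALSE)
  sidecar <- utils::read.csv(p$features)
  corr <- if (!is.null(cfg$corrections_csv) && file.exists(cfg$corrections_csv))
    utils::read.csv(cfg$corrections_csv)
  all_lm <- list(); all_rise <- list(); all_feat <- list(); waves <- list()
  excl <- list()
  for (sid in sent_ids(cfg)) {
    wav_path <- file.path(p$audio, paste0(sid, ".wav"))
    tg_path <- file.path(p$textgrids, paste0(sid, ".TextGrid"))
    if (!file.exists(wav_path)) stop("missing audio: ", wav_path,
                                     call. = FALSE)
    w <- read_wav(wav_path)
    syl <- textgrid_syllables(read_textgrid(tg_path), sentence_id = sid)
    syl <- syl[order(syl$syllable_idx), ]
    chain <- energy_chain(w, cfg$window_s, cfg$smooth_order, cfg$diff_order,
                          cfg$zcr_threshold, cfg$zcr_factor)
    iv <- syl[, c("sentence_id", "syllable_idx", "start_s", "end_s")]
    lm <- maxd_landmarks(chain$difference, iv)
    ov <- NULL
    if (!is.null(corr)) {
      m <- match(paste(sid, syl$syllable_idx),
                 paste(corr$sentence_id, corr$syllable_idx))
      if (any(!is.na(m))) ov <- corr$override_min_s[m]
    }
    rises <- rise_table(chain$smoothed, chain$difference, iv, overrides = ov)
    ann <- merge(syl, sidecar, by = c("sentence_id", "syllable_idx"))
    ann <- ann[order(ann$syllable_idx), ]
    ft <- build_feature_table(ann, rises, w)
    all_lm[[sid]] <- lm
    all_rise[[sid]] <- rises
    all_feat[[sid]] <- ft
    excl[[sid]] <- attr(ft, "exclusions")
    waves[[sid]] <- w
  }
  feat <- do.call(rbind, all_feat)
  rownames(feat) <- NULL
  write_tab(do.call(rbind, all_lm), file.path(p$results, "landmarks.csv"))
  write_tab(do.call(rbind, all_rise), file.path(p$results, "rises.csv"))
  write_tab(feat, file.path(p$results, "feature_table.csv"))
  write_tab(do.call(rbind, excl), file.path(p$results, "exclusions.csv"))
  invisible(feat)
}

# read one participant-sentence tap file (MIDI preferred, CSV fallback)
read_tap_file <- function(taps_dir, sid, pid) {
  mid <- file.path(taps_dir, sprintf("%s_%s.mid", sid, pid))
  csv <- file.path(taps_dir, sprintf("%s_%s.csv", sid, pid))
  if (file.exists(mid)) read_midi_taps(mid)
  else if (file.exists(csv)) utils::read.csv(csv)$tap_time_s
  else NULL
}

#' Run the sensorimotor-synchronization stage
#'
#' Reads the tap recordings, subtracts the recording latency, folds taps
#' into repetition cycles (discarding the first \code{skip_reps}), estimates
#' the per-participant tapping density with 1/8 of the normal-reference
#' bandwidth, picks density peaks, anchors them to the maxD landmarks of
#' the acoustic stage within +/-120 ms, and aggregates signed and absolute
#' asynchronies by item. Writes \code{peaks.csv}, \code{asynchrony.csv} and
#' \code{item_asynchrony.csv} under \code{<out_dir>/results}.
#'
#' @param cfg An [rt_config].
#' @return Invisibly, the item-level asynchrony table (zero rows, with a
#'   warning, when no taps anchored).
#' @export
run_sms <- function(cfg) {
  stopifnot(inherits(cfg, "rt_config"))
  p <- cfg_paths(cfg)
  dir.create(p$results, recursive = TRUE, showWarnings = FALSE)
  loops <- utils::read.csv(p$loops)
  landmarks <- utils::read.csv(file.path(p$results, "landmarks.csv"))
  pids <- sprintf("P%02d", seq_len(cfg$n_participants))
  peaks_rows <- list(); asyn_rows <- list()
  for (sid in sent_ids(cfg)) {
    loop <- loops[loops$sentence_id == sid, ]
    lms <- landmarks[landmarks$sentence_id == sid, ]
    for (pid in pids) {
      taps <- read_tap_file(p$taps, sid, pid)
      if (is.null(taps) || length(taps) < 2L) next
      taps <- correct_latency(taps, cfg$latency_s)
      folded <- fold_cycles(taps, loop$cycle_dur_s, loop$n_reps,
                            cfg$skip_reps, cfg$lead_s)
      if (nrow(folded) < 2L ||
          length(unique(folded$rel_time_s)) < 2L) next
      dens <- tap_density(folded$rel_time_s, bw_divisor = cfg$bw_divisor)
      pk <- find_tap_peaks(dens, cfg$rel_threshold, cfg$min_sep_s)
      if (nrow(pk) == 0L) next
      pk2 <- cbind(participant_id = pid, sentence_id = sid, pk)
      peaks_rows[[length(peaks_rows) + 1L]] <- pk2
      a <- anchor_peaks(pk, lms, cfg$window_ms)
      if (nrow(a) > 0L)
        asyn_rows[[length(asyn_rows) + 1L]] <-
          cbind(participant_id = pid, sentence_id = sid, a)
    }
  }
  peaks <- do.call(rbind, peaks_rows)
  if (is.null(peaks))
    peaks <- data.frame(participant_id = character(0),
                        sentence_id = character(0), time_s = numeric(0),
                        density_value = numeric(0))
  write_tab(peaks, file.path(p$results, "peaks.csv"))
  asyn <- do.call(rbind, asyn_rows)
  if (is.null(asyn) || nrow(asyn) == 0L) {
    warning("no taps anchored to any landmark; asynchrony tables are empty")
    asyn <- data.frame(participant_id = character(0),
                       sentence_id = character(0),
                       syllable_idx = integer(0), landmark_s = numeric(0),
                       peak_s = numeric(0), signed_ms = numeric(0),
                       abs_ms = numeric(0))
    item <- data.frame(sentence_id = character(0), syllable_idx = integer(0),
                       median_signed_ms = numeric(0),
                       median_abs_ms = numeric(0),
                       n_participants = integer(0))
  } else {
    item <- aggregate_by_item(asyn)
  }
  write_tab(asyn, file.path(p$results, "asynchrony.csv"))
  write_tab(item, file.path(p$results, "item_asynchrony.csv"))
  invisible(item)
}

#' Run the regression stage
#'
#' Joins the feature table with the item-level asynchronies, log-transforms
#' rise-time and absolute asynchrony (millisecond scale), and fits the three
#' analyses -- rise-time, absolute asynchrony and signed asynchrony -- each
#' as a fully specified model followed by backward elimination, a nested
#' comparison against the full model, and VIFs; plus the predictor
#' correlation matrix at the adjusted alpha. Coefficient tables are written
#' in the conventional layout (Factor, b, SE, t, CI_low, CI_high, beta).
#'
#' @param cfg An [rt_config].
#' @return Invisibly, a named list of [backward_eliminate] results.
#' @export
run_models <- function(cfg) {
  stopifnot(inherits(cfg, "rt_config"))
  p <- cfg_paths(cfg)
  feat <- utils::read.csv(file.path(p$results, "feature_table.csv"))
  item <- utils::read.csv(file.path(p$results, "item_asynchrony.csv"))
  tab <- merge(feat, item, by = c("sentence_id", "syllable_idx"))
  tab$weight <- factor(tab$weight, levels = c("weak", "strong"))
  tab$onset_complexity <- factor(tab$onset_complexity, levels = c(0, 1, 2))
  tab$serial_order <- tab$syllable_idx
  tab$rise_time_ms <- tab$rise_time_s * 1000
  tab <- prepare_responses(tab)
  write_tab(tab, file.path(p$results, "item_table.csv"))
  norm <- attr(tab, "normality")
  if (!is.null(norm))
    write_tab(norm, file.path(p$results, "normality.csv"))

  base_terms <- c("rise_slope", "nucleus_dur_s", "weight",
                  "onset_complexity", "sonority", "rel_intensity",
                  "serial_order")
  analyses <- list(
    rise_time = list(response = "log_rise_time_ms", terms = base_terms),
    abs_asynchrony = list(response = "log_median_abs_ms",
                          terms = c("log_rise_time_ms", base_terms)),
    signed_asynchrony = list(response = "median_signed_ms",
                             terms = c("log_rise_time_ms", base_terms)))
  out <- list()
  for (nm in names(analyses)) {
    an <- analyses[[nm]]
    full <- fit_lm(tab, an$response, an$terms)
    be <- backward_eliminate(full, alpha = cfg$alpha)
    out[[nm]] <- be
    co <- be$final$coefficients
    report <- data.frame(Factor = co$term, b = co$b, SE = co$se, t = co$t,
                         CI_low = co$ci_low, CI_high = co$ci_high,
                         beta = co$beta_std)
    write_tab(report,
              file.path(p$results, sprintf("model_%s_coefficients.csv", nm)))
    write_tab(be$comparison,
              file.path(p$results, sprintf("model_%s_comparison.csv", nm)))
    write_tab(vif(tab, an$terms),
              file.path(p$results, sprintf("model_%s_vif.csv", nm)))
  }
  num_terms <- c("rise_slope", "nucleus_dur_s", "sonority", "rel_intensity",
                 "serial_order", "log_rise_time_ms")
  pc <- predictor_correlations(tab, num_terms, alpha = cfg$corr_alpha)
  corr_df <- as.data.frame(as.table(pc$r))
  names(corr_df) <- c("var1", "var2", "r")
  corr_df$p <- as.vector(pc$p)
  corr_df$significant <- as.vector(pc$significant)
  write_tab(corr_df, file.path(p$results, "predictor_correlations.csv"))
  invisible(out)
}

#' Run the full pipeline
#'
#' [run_simulate], [run_acoustics], [run_sms] and [run_models] in sequence.
#' Deterministic (bit-identical output files) for a fixed \code{cfg$seed}.
#'
#' @param cfg An [rt_config].
#' @return Invisibly, the [run_models] result list.
#' @export
run_pipeline <- function(cfg) {
  run_simulate(cfg)
  run_acoustics(cfg)
  run_sms(cfg)
  run_models(cfg)
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{acoustics}, \code{sms}, \code{model},
#' \code{all}. Flags: \code{--out-dir=PATH} (required), \code{--seed=INT},
#' plus \code{--sentences=}, \code{--participants=}, \code{--reps=} to
#' resize the synthetic corpus. Typical use:
#' \code{Rscript -e 'risetap::rt_cli()' all --out-dir=run1 --seed=7}.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, NULL.
#' @export
rt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: rt_cli <simulate|acoustics|sms|model|all>",
                 "--out-dir=PATH [--seed=INT] [--sentences=N]",
                 "[--participants=N] [--reps=N]")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1]
  if (!cmd %in% c("simulate", "acoustics", "sms", "model", "all"))
    stop(usage, call. = FALSE)
  flag <- function(name, default = NULL) {
    hit <- grep(paste0("^--", name, "="), args, value = TRUE)
    if (length(hit) == 0L) default else sub(paste0("^--", name, "="), "",
                                            hit[1])
  }
  out_dir <- flag("out-dir")
  if (is.null(out_dir)) stop(usage, call. = FALSE)
  cfg <- rt_config(out_dir, seed = as.integer(flag("seed", "1")),
                   n_sentences = as.integer(flag("sentences", "10")),
                   n_participants = as.integer(flag("participants", "12")),
                   n_reps = as.integer(flag("reps", "15")))
  switch(cmd,
         simulate = run_simulate(cfg),
         acoustics = run_acoustics(cfg),
         sms = run_sms(cfg),
         model = run_models(cfg),
         all = run_pipeline(cfg))
  message("done: ", cmd, " -> ", out_dir)
  invisible(NULL)
}
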