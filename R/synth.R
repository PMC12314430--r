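# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthesize a tone with a piecewise-linear amplitude envelope
#'
#' Sine carrier with a linear amplitude rise over \code{rise_s}, a plateau
#' at \code{amp}, and a linear fall over the final \code{fall_s}. The
#' envelope reaches \code{amp} exactly at t = \code{rise_s}; a zero rise
#' gives a step onset.
#'
#' @param duration_s Total duration in seconds.
#' @param freq_hz Carrier frequency in Hz.
#' @param rise_s Linear rise duration (>= 0).
#' @param fall_s Linear fall duration (>= 0).
#' @param amp Plateau amplitude in \[0, 1\].
#' @param rate_hz Sample rate (>= 8000, default 44100).
#' @return An [rt_wave].
#' @export
synth_tone <- function(duration_s, freq_hz, rise_s, fall_s, amp,
                       rate_hz = 44100) {
  if (rise_s < 0 || fall_s < 0 || rise_s + fall_s > duration_s + 1e-12)
    stop("need rise_s + fall_s <= duration_s with nonnegative ramps",
         call. = FALSE)
  if (rate_hz < 8000)
    stop("`rate_hz` must be at least 8000", call. = FALSE)
  if (amp < 0 || amp > 1)
    stop("`amp` must lie in [0, 1]", call. = FALSE)
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  env <- trapezoid_env(t, duration_s, rise_s, fall_s, amp)
  rt_wave(env * sin(2 * pi * freq_hz * t), rate_hz)
}

trapezoid_env <- function(t, duration_s, rise_s, fall_s, amp) {
  env <- rep(amp, length(t))
  if (rise_s > 0) {
    i <- t < rise_s
    env[i] <- amp * t[i] / rise_s
  }
  if (fall_s > 0) {
    i <- t > duration_s - fall_s
    env[i] <- amp * pmax(duration_s - t[i], 0) / fall_s
  }
  env
}

#' Syllable specification for the sentence synthesizer
#'
#' Parametric description of one synthetic syllable: a linear onset
#' amplitude ramp of known duration, a nucleus plateau, and a linear decay,
#' riding on a harmonic carrier (f0 plus two partials) so that intensity and
#' zero-crossing behaviour are speech-like. Fricative onsets use
#' high-frequency noise during the ramp so their frames exceed the
#' zero-crossing threshold of the fricative-attenuation branch.
#'
#' @param onset_ramp_s Linear rise duration (s, > 0).
#' @param onset_type One of \code{"none"}, \code{"sonorant"},
#'   \code{"obstruent"}, \code{"fricative"}.
#' @param nucleus_dur_s Nucleus (plateau) duration (s, > 0).
#' @param peak_amp Plateau amplitude in (0, 1\].
#' @param decay_s Decay duration (s, >= 0).
#' @param f0_hz Carrier fundamental (Hz).
#' @param weight Metrical weight, \code{"strong"} or \code{"weak"}.
#' @param onset_complexity Number of onset consonants, 0--3.
#' @param sonority Average onset sonority, 0--9.
#' @return A list of class \code{syllable_spec}.
#' @export
syllable_spec <- function(onset_ramp_s, onset_type = c("none", "sonorant",
                                                       "obstruent",
                                                       "fricative"),
                          nucleus_dur_s, peak_amp = 0.8, decay_s = 0.05,
                          f0_hz = 200, weight = c("weak", "strong"),
                          onset_complexity = 0L, sonority = 9) {
  onset_type <- match.arg(onset_type)
  weight <- match.arg(weight)
  if (onset_ramp_s <= 0) stop("`onset_ramp_s` must be > 0", call. = FALSE)
  if (nucleus_dur_s <= 0) stop("`nucleus_dur_s` must be > 0", call. = FALSE)
  if (peak_amp <= 0 || peak_amp > 1)
    stop("`peak_amp` must lie in (0, 1]", call. = FALSE)
  if (decay_s < 0) stop("`decay_s` must be >= 0", call. = FALSE)
  if (!onset_complexity %in% 0:3)
    stop("`onset_complexity` must be 0..3", call. = FALSE)
  if (sonority < 0 || sonority > 9)
    stop("`sonority` must lie in [0, 9]", call. = FALSE)
  structure(list(onset_ramp_s = onset_ramp_s, onset_type = onset_type,
                 nucleus_dur_s = nucleus_dur_s, peak_amp = peak_amp,
                 decay_s = decay_s, f0_hz = f0_hz, weight = weight,
                 onset_complexity = as.integer(onset_complexity),
                 sonority = sonority),
            class = "syllable_spec")
}

# harmonic complex carrier (f0 + 2 partials), peak-normalized
harmonic_carrier <- function(t, f0) {
  x <- sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t) +
    0.25 * sin(2 * pi * 3 * f0 * t)
  x / 1.75
}

# high-ZCR noise carrier: first difference of white noise (high-pass),
# scaled to unit peak
fricative_carrier <- function(n) {
  x <- diff(c(0, stats::rnorm(n)))
  x / max(abs(x), 1e-12)
}

#' Synthesize an annotated sentence-like waveform
#'
#' Concatenates parametric syllables separated (and flanked) by silences of
#' \code{gap_s}. Each syllable's amplitude envelope rises linearly over its
#' onset ramp, holds through the nucleus, and decays linearly; the carrier
#' is a harmonic complex except during fricative onsets, which use
#' high-frequency noise. The returned annotation carries ground-truth
#' syllable and nucleus boundaries and the true ramp start and end per
#' syllable. Deterministic given \code{seed} (noise onsets are the only
#' stochastic component).
#'
#' @param specs List of [syllable_spec] (at least one).
#' @param gap_s Silence between syllables and at both ends (default 0.05 s).
#' @param rate_hz Sample rate (default 44100).
#' @param seed Optional integer seed.
#' @param sentence_id Sentence identifier carried into the annotation
#'   (default \code{"s1"}).
#' @return List with \code{wave} (an [rt_wave]) and \code{annotation}
#'   (data frame: sentence_id, syllable_idx, start_s, end_s,
#'   nucleus_start_s, nucleus_end_s, ramp_start_s, ramp_end_s, peak_amp,
#'   weight, onset_complexity, sonority, onset_type, f0_hz).
#' @export
synth_sentence <- function(specs, gap_s = 0.05, rate_hz = 44100,
                           seed = NULL, sentence_id = "s1") {
  if (length(specs) < 1L) stop("need at least one syllable spec",
                               call. = FALSE)
  if (inherits(specs, "syllable_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "syllable_spec")))
  with_seed(seed, {
    pieces <- list(numeric(round(gap_s * rate_hz)))
    rows <- vector("list", length(specs))
    cursor <- gap_s
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      dur <- sp$onset_ramp_s + sp$nucleus_dur_s + sp$decay_s
      n <- round(dur * rate_hz)
      t <- (seq_len(n) - 1L) / rate_hz
      # vowel amplitude peaks at the nucleus onset and declines mildly
      # through the nucleus (as in natural speech), so the energy maximum
      # is a genuine corner rather than a ripple-dominated plateau
      env <- stats::approx(
        c(0, sp$onset_ramp_s, sp$onset_ramp_s + sp$nucleus_dur_s, dur),
        c(0, sp$peak_amp, 0.85 * sp$peak_amp, 0),
        t, rule = 2)$y
      carrier <- harmonic_carrier(t, sp$f0_hz)
      if (sp$onset_type == "fricative") {
        i_ramp <- t < sp$onset_ramp_s
        carrier[i_ramp] <- fricative_carrier(sum(i_ramp))
      } else if (sp$onset_type == "obstruent") {
        burst_n <- min(round(0.010 * rate_hz), n)
        carrier[seq_len(burst_n)] <- fricative_carrier(burst_n)
      }
      pieces[[length(pieces) + 1L]] <- env * carrier
      pieces[[length(pieces) + 1L]] <- numeric(round(gap_s * rate_hz))
      rows[[i]] <- data.frame(
        sentence_id = sentence_id, syllable_idx = i,
        start_s = cursor, end_s = cursor + dur,
        nucleus_start_s = cursor + sp$onset_ramp_s,
        nucleus_end_s = cursor + sp$onset_ramp_s + sp$nucleus_dur_s,
        ramp_start_s = cursor, ramp_end_s = cursor + sp$onset_ramp_s,
        peak_amp = sp$peak_amp, weight = sp$weight,
        onset_complexity = sp$onset_complexity, sonority = sp$sonority,
        onset_type = sp$onset_type, f0_hz = sp$f0_hz)
      cursor <- cursor + dur + gap_s
    }
    list(wave = rt_wave(unlist(pieces), rate_hz),
         annotation = do.call(rbind, rows))
  })
}

#' Tap-train simulation specification
#'
#' @param anchor_times_s Planted anchor times within one cycle (all in
#'   \[0, cycle_dur_s)).
#' @param cycle_dur_s Cycle duration (s).
#' @param n_cycles Number of repetition cycles (>= 3).
#' @param n_participants Number of simulated participants.
#' @param jitter_sd_s Gaussian timing jitter SD (s).
#' @param bias_s Constant timing bias (s; negative = anticipation).
#' @param miss_prob Per-anchor miss probability in \[0, 1\].
#' @param start_cycle First cycle in which taps are produced (default 3:
#'   participants start tapping from the third repetition).
#' @param seed Optional integer seed.
#' @return A list of class \code{tap_sim_spec}.
#' @export
tap_sim_spec <- function(anchor_times_s, cycle_dur_s, n_cycles,
                         n_participants = 1L, jitter_sd_s = 0,
                         bias_s = 0, miss_prob = 0, start_cycle = 3L,
                         seed = NULL) {
  if (n_cycles < 3) stop("`n_cycles` must be >= 3", call. = FALSE)
  if (any(anchor_times_s < 0 | anchor_times_s >= cycle_dur_s))
    stop("anchors must lie in [0, cycle_dur_s)", call. = FALSE)
  if (miss_prob < 0 || miss_prob > 1)
    stop("`miss_prob` must lie in [0, 1]", call. = FALSE)
  if (jitter_sd_s < 0) stop("`jitter_sd_s` must be >= 0", call. = FALSE)
  structure(list(anchor_times_s = sort(anchor_times_s),
                 cycle_dur_s = cycle_dur_s, n_cycles = as.integer(n_cycles),
                 n_participants = as.integer(n_participants),
                 jitter_sd_s = jitter_sd_s, bias_s = bias_s,
                 miss_prob = miss_prob, start_cycle = as.integer(start_cycle),
                 seed = seed),
            class = "tap_sim_spec")
}

#' Simulate looped tap trains
#'
#' For each participant, cycle (from \code{start_cycle} on) and anchor, a
#' tap is emitted with probability 1 - \code{miss_prob} at
#' \code{cycle_onset + anchor + bias + Normal(0, jitter_sd)}. Reproducible
#' under the specification's seed field.
#'
#' @param spec A [tap_sim_spec].
#' @return Named list (P01, P02, ...) of sorted numeric tap-time vectors;
#'   empty vectors when everything is missed.
#' @export
synth_taps <- function(spec) {
  stopifnot(inherits(spec, "tap_sim_spec"))
  with_seed(spec$seed, {
    cycles <- seq(spec$start_cycle, spec$n_cycles)
    onsets <- (cycles - 1) * spec$cycle_dur_s
    base <- as.vector(outer(spec$anchor_times_s, onsets, "+"))
    out <- lapply(seq_len(spec$n_participants), function(p) {
      hit <- stats::runif(length(base)) >= spec$miss_prob
      t <- base[hit] + spec$bias_s +
        stats::rnorm(sum(hit), 0, spec$jitter_sd_s)
      sort(pmax(t, 0))
    })
    names(out) <- sprintf("P%02d", seq_len(spec$n_participants))
    out
  })
}

#' Simulate a per-syllable feature table from a planted linear model
#'
#' Draws predictors with realistic ranges (serial order 1--13, Bernoulli
#' metrical weight, categorical onset complexity 0--2, sonority 0--9,
#' log-normal nucleus duration and rise-slope, intensity around 1) and a
#' response \code{y = X b + Normal(0, noise_sd)} from the planted
#' coefficient vector. Used for parameter-recovery and elimination tests.
#'
#' @param n Number of rows (>= number of coefficients + 2).
#' @param coefficients Named numeric vector over the expanded model-matrix
#'   columns; see [planted_coefficients] for the column names and a
#'   plausible default.
#' @param noise_sd Residual SD (0 gives an exact linear response).
#' @param seed Optional integer seed.
#' @return Data frame with the predictor columns, \code{y}, and attribute
#'   \code{"coefficients"} (the planted vector, in model-matrix order).
#' @export
synth_feature_table <- function(n, coefficients = planted_coefficients(),
                                noise_sd = 0.5, seed = NULL) {
  if (n < length(coefficients) + 2L)
    stop("`n` must be at least length(coefficients) + 2", call. = FALSE)
  with_seed(seed, synth_feature_table_once(n, coefficients, noise_sd))
}

synth_feature_table_once <- function(n, coefficients, noise_sd,
                                     attempt = 1L) {
  tab <- data.frame(
    serial_order = sample(1:13, n, replace = TRUE),
    weight = factor(ifelse(stats::rbinom(n, 1, 0.5) == 1,
                           "strong", "weak"), levels = c("weak", "strong")),
    onset_complexity = factor(sample(0:2, n, replace = TRUE,
                                     prob = c(0.35, 0.45, 0.20)),
                              levels = c(0, 1, 2)),
    sonority = stats::runif(n, 0, 9),
    nucleus_dur_s = stats::rlnorm(n, log(0.12), 0.4),
    rel_intensity = stats::rnorm(n, 1, 0.08),
    rise_slope = stats::rlnorm(n, log(5), 0.5))
  X <- stats::model.matrix(~ serial_order + weight + onset_complexity +
                             sonority + nucleus_dur_s + rel_intensity +
                             rise_slope, data = tab)
  miss <- setdiff(names(coefficients), colnames(X))
  if (length(miss) > 0L)
    stop("coefficient name(s) not in the model matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    if (attempt > 5L)
      stop("could not draw a non-singular design", call. = FALSE)
    warning("singular design; regenerating with a fresh draw")
    return(synth_feature_table_once(n, coefficients, noise_sd, attempt + 1L))
  }
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  b[names(coefficients)] <- coefficients
  tab$y <- as.vector(X %*% b) + stats::rnorm(n, 0, noise_sd)
  attr(tab, "coefficients") <- b
  tab
}

#' Default planted coefficients for [synth_feature_table]
#'
#' Magnitudes chosen so that, with the generator's predictor distributions
#' and \code{noise_sd = 0.5}, the planted model explains roughly a third of
#' the response variance -- comparable to a moderate-effect per-syllable
#' regression.
#'
#' @return Named numeric vector over the expanded model-matrix columns.
#' @export
planted_coefficients <- function() {
  c("(Intercept)" = 3.0, serial_order = -0.02, weightstrong = 0.18,
    onset_complexity1 = 0.25, onset_complexity2 = 0.45, sonority = 0.03,
    nucleus_dur_s = 1.2, rel_intensity = 0.6, rise_slope = 0.05)
}
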