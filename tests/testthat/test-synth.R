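test_that("synth_tone builds the requested trapezoid envelope", {
  w <- synth_tone(0.5, 500, 0.025, 0.05, 0.8, 44100)
  expect_equal(duration(w), 0.5)
  # envelope reaches 0.8 at t = 25 ms: peak |sample| within one carrier
  # period of the ramp end equals the plateau amplitude
  i <- which(abs(seq_along(w$samples) / 44100 - 0.026) < 0.002)
  expect_gt(max(abs(w$samples[i])), 0.79)
  # still on the ramp at 12.5 ms: envelope at half height
  i <- which(abs(seq_along(w$samples) / 44100 - 0.0125) < 0.001)
  expect_lt(max(abs(w$samples[i])), 0.45)

  step <- synth_tone(0.1, 500, 0, 0.01, 0.7)
  i <- seq_len(round(0.002 * 44100))   # a full period right at onset
  expect_gt(max(abs(step$samples[i])), 0.69)

  expect_equal(synth_tone(0.1, 500, 0.01, 0.01, 0)$samples,
               rep(0, round(0.1 * 44100)))
  expect_error(synth_tone(0.1, 500, 0.08, 0.05, 0.5), "rise_s \\+ fall_s")
  expect_error(synth_tone(0.5, 500, 0.01, 0.01, 0.5, rate_hz = 4000),
               "8000")
})

test_that("synth_sentence returns consistent ground-truth annotation", {
  specs <- lapply(1:8, function(i)
    syllable_spec(0.02 + 0.01 * i, "sonorant", 0.12, peak_amp = 0.7))
  syn <- synth_sentence(specs, gap_s = 0.05, seed = 11)
  ann <- syn$annotation
  expect_equal(nrow(ann), 8L)
  expect_true(all(diff(ann$start_s) > 0))
  expect_true(all(ann$end_s > ann$start_s))
  expect_true(all(ann$nucleus_start_s >= ann$start_s &
                    ann$nucleus_end_s <= ann$end_s + 1e-9))
  expect_equal(ann$ramp_end_s - ann$ramp_start_s,
               0.02 + 0.01 * (1:8))
  # determinism: same seed, bit-identical waveform
  syn2 <- synth_sentence(specs, gap_s = 0.05, seed = 11)
  expect_identical(syn$wave$samples, syn2$wave$samples)
  expect_error(synth_sentence(list()), "at least one")
})

test_that("synth_taps plants anchors with the requested noise model", {
  anchors <- c(0.5, 1.2, 2.0)
  clean <- tap_sim_spec(anchors, 3, 6, n_participants = 2,
                        jitter_sd_s = 0, bias_s = 0, miss_prob = 0,
                        seed = 3)
  taps <- synth_taps(clean)
  expect_named(taps, c("P01", "P02"))
  expected <- sort(as.vector(outer(anchors, (2:5) * 3, "+")))
  expect_equal(taps$P01, expected)
  expect_equal(taps$P02, expected)

  none <- synth_taps(tap_sim_spec(anchors, 3, 6, miss_prob = 1, seed = 3))
  expect_length(none$P01, 0L)

  # signed bias recovers in the sample mean over >= 1000 taps
  biased <- tap_sim_spec(anchors, 3, 120, n_participants = 3,
                         jitter_sd_s = 0.02, bias_s = -0.03,
                         miss_prob = 0, seed = 9)
  tt <- synth_taps(biased)
  asyn <- unlist(lapply(tt, function(t)
    t - sort(as.vector(outer(anchors, (2:119) * 3, "+")))))
  expect_gt(length(asyn), 1000L)
  se <- 0.02 / sqrt(length(asyn))
  expect_lt(abs(mean(asyn) + 0.03), 4 * se)

  expect_error(tap_sim_spec(c(0.5, 3.5), 3, 6), "anchors")
  expect_error(tap_sim_spec(0.5, 3, 2), "n_cycles")
})

test_that("synth_feature_table embeds the planted linear model", {
  exact <- synth_feature_table(60, noise_sd = 0, seed = 21)
  b <- attr(exact, "coefficients")
  fit <- suppressWarnings(  # lm warns on an essentially perfect fit
    fit_lm(exact, "y", c("serial_order", "weight", "onset_complexity",
                         "sonority", "nucleus_dur_s", "rel_intensity",
                         "rise_slope")))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  est <- setNames(fit$coefficients$b, fit$coefficients$term)
  expect_equal(est[names(b)], b, tolerance = 1e-8)

  expect_error(synth_feature_table(5), "at least")
  # determinism
  t1 <- synth_feature_table(40, noise_sd = 0.5, seed = 5)
  t2 <- synth_feature_table(40, noise_sd = 0.5, seed = 5)
  expect_identical(t1, t2)
})
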