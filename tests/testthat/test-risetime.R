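test_that("local_energy_maximum finds hump apices and flags edge cases", {
  # single hump
  v <- dnorm(seq(-3, 3, length.out = 121))
  e <- rt_contour(v, kind = "smoothed")
  got <- local_energy_maximum(e, c(0, 0.121))
  expect_equal(got$time_s, 0.060)
  expect_false(got$degenerate)

  # equals exhaustive argmax on rough contours (no near-ties)
  set.seed(31)
  for (i in 1:50) {
    v <- abs(rnorm(150)) + 0.01
    e <- rt_contour(v, kind = "smoothed")
    a <- c(0.02, 0.13)
    want <- oracle_argmax(v, 0, a[1], a[2])
    expect_identical(local_energy_maximum(e, a)$time_s, want$time_s)
  }

  # monotonically rising syllable -> last frame, degenerate flag
  rising <- rt_contour(seq(0, 1, length.out = 100), kind = "smoothed")
  got <- local_energy_maximum(rising, c(0, 0.1))
  expect_equal(got$time_s, 0.099)
  expect_true(got$degenerate)
})

test_that("find_preceding_minimum implements the 70% slope-drop rule", {
  # flat at 0.1 until 1.000 s, then steep rise to a max at 1.050 s
  t <- seq(0, 1.1, by = 0.001)
  v <- ifelse(t < 1, 0.1, 0.1 + pmin(t - 1, 0.05) * 20)
  e <- rt_contour(v, kind = "smoothed")
  got <- find_preceding_minimum(e, 1.050)
  expect_false(got$flagged)
  expect_lt(abs(got$time_s - 1.000), 0.006)

  # hand-built slope sequence 2.0, 2.0, 0.4 (per 5 ms, backward from max):
  # 0.4 / 2.0 = 0.2 < 0.3 qualifies; foot at the boundary between steps
  seg <- c(rep(0.3, 81),                       # flat approach
           0.3 + cumsum(rep(0.4 * 0.005 / 5, 5)),   # slope 0.4 over 5 ms
           0.302 + cumsum(rep(2.0 * 0.005 / 5, 10))) # slope 2.0 over 10 ms
  e2 <- rt_contour(seg, kind = "smoothed")
  t_max <- (length(seg) - 1) * 0.001          # 0.095 s
  got2 <- find_preceding_minimum(e2, t_max)
  expect_false(got2$flagged)
  expect_equal(got2$time_s, t_max - 0.010)

  # globally flat contour -> fallback path, review flag
  flat <- rt_contour(rep(0.2, 200), kind = "smoothed")
  got3 <- find_preceding_minimum(flat, 0.150)
  expect_true(got3$flagged)
})

test_that("rise_measurement combines searches and applies overrides", {
  # piecewise-linear rise from (0.100 s, 0.02) to (0.150 s, 0.42)
  t <- seq(0, 0.3, by = 0.001)
  v <- approx(c(0, 0.1, 0.15, 0.3), c(0.02, 0.02, 0.42, 0.02), t)$y
  e <- rt_contour(v, kind = "smoothed")
  d <- energy_difference(e)
  syll <- c(0.05, 0.25)
  m <- rise_measurement(e, syll, find_maxD(d, syll))
  expect_equal(m$t_max_s, 0.150)
  expect_equal(m$rise_time_s, 0.150 - m$t_min_s)
  expect_lt(abs(m$t_min_s - 0.100), 0.011)
  expect_equal(m$rise_slope, (m$e_max - m$e_min) / m$rise_time_s)
  # hand arithmetic at the exact landmark pair
  expect_equal((0.42 - 0.02) / 0.050, 8.0)

  ov <- rise_measurement(e, syll, find_maxD(d, syll),
                         override_min_s = 0.095)
  expect_true(ov$corrected)
  expect_equal(ov$t_min_s, 0.095)
  expect_error(rise_measurement(e, syll, find_maxD(d, syll),
                                override_min_s = 0.20), "precede")
})

test_that("measured rise-time grows with ramp duration; slope scales c^2", {
  r25 <- ramp_tone_chain(0.025)
  r50 <- ramp_tone_chain(0.050)
  m25 <- rise_measurement(r25$chain$smoothed, r25$syll,
                          find_maxD(r25$chain$difference, r25$syll))
  m50 <- rise_measurement(r50$chain$smoothed, r50$syll,
                          find_maxD(r50$chain$difference, r50$syll))
  expect_false(m25$flagged || m50$flagged)
  expect_equal((m50$rise_time_s - m25$rise_time_s) * 1000, 25,
               tolerance = 5 / 25)
  # maxD spanned by the rise interval
  md <- find_maxD(r25$chain$difference, r25$syll)
  expect_true(m25$t_min_s <= md$time_s && md$time_s <= m25$t_max_s)

  # amplitude scaling: rise-time invariant, rise-slope scales by c^2
  sc <- rt_wave(r25$wave$samples * 2, r25$wave$rate_hz)
  ch <- energy_chain(sc)
  msc <- rise_measurement(ch$smoothed, r25$syll,
                          find_maxD(ch$difference, r25$syll))
  expect_equal(msc$rise_time_s, m25$rise_time_s)
  expect_equal(msc$rise_slope, 4 * m25$rise_slope, tolerance = 1e-6)
})

test_that("hilbert backend recovers ramps and correlates with energy", {
  w <- synth_tone(0.6, 500, 0.050, 0.05, 0.8, 22050)
  pad <- rt_wave(c(numeric(round(0.15 * 22050)), w$samples,
                   numeric(round(0.15 * 22050))), 22050)
  h <- hilbert_rise(pad, c(0.15, 0.75))
  expect_false(is.na(h$rise_time_s))
  expect_equal(h$rise_time_s, 0.050, tolerance = 10 / 50)

  # constant-amplitude tone: flat envelope, review flag
  const <- rt_wave(sin(2 * pi * 500 * (0:11025) / 22050), 22050)
  expect_true(hilbert_rise(const, c(0.05, 0.45))$flagged)

  # both backends agree in rank across a small synthetic corpus
  set.seed(17)
  ramps <- c(0.015, 0.025, 0.04, 0.06, 0.08, 0.1, 0.02, 0.05)
  specs <- lapply(ramps, function(r)
    syllable_spec(r, "sonorant", runif(1, 0.1, 0.2),
                  peak_amp = runif(1, 0.5, 0.9)))
  syn <- synth_sentence(specs, gap_s = 0.25, rate_hz = 22050, seed = 2)
  ch <- energy_chain(syn$wave)
  rt_e <- rt_h <- numeric(nrow(syn$annotation))
  prev <- NULL
  for (i in seq_len(nrow(syn$annotation))) {
    syll <- c(syn$annotation$start_s[i], syn$annotation$end_s[i])
    m <- rise_measurement(ch$smoothed, syll, find_maxD(ch$difference, syll),
                          prev_max_s = prev)
    prev <- m$t_max_s
    rt_e[i] <- m$rise_time_s
    rt_h[i] <- hilbert_rise(syn$wave, syll)$rise_time_s
  }
  expect_gt(cor(rt_e, rt_h, use = "complete.obs"), 0.5)
})
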