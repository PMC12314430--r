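test_that("raw_energy matches closed forms on elementary signals", {
  rate <- 44100
  silence <- rt_wave(rep(0, rate / 2), rate)
  expect_true(all(raw_energy(silence)$values == 0))

  const <- rt_wave(rep(0.6, rate / 2), rate)
  e <- raw_energy(const)
  interior <- e$values[50:450]
  expect_equal(interior, rep(0.36, length(interior)), tolerance = 1e-12)

  sine <- rt_wave(sin(2 * pi * 1000 * (0:(rate / 2)) / rate), rate)
  es <- raw_energy(sine)
  expect_equal(mean(es$values[100:400]), 0.5, tolerance = 1e-3)

  expect_error(raw_energy(rt_wave(rep(0.1, 100), rate)), "40-ms")
  # frame grid: 1-ms hop starting at t = 0
  expect_equal(frame_times(e)[1:3], c(0, 0.001, 0.002))
})

test_that("zero_crossing_rate approximates 2f per second on sinusoids", {
  rate <- 44100
  t <- (0:(rate / 2)) / rate
  dc <- rt_wave(rep(0.5, rate / 2), rate)
  expect_true(all(zero_crossing_rate(dc)$values == 0))
  z4k <- zero_crossing_rate(rt_wave(sin(2 * pi * 4000 * t), rate))
  expect_equal(mean(z4k$values[100:400]), 8, tolerance = 0.05)
  z1k <- zero_crossing_rate(rt_wave(sin(2 * pi * 1000 * t), rate))
  expect_equal(mean(z1k$values[100:400]), 2, tolerance = 0.05)
  expect_true(all(z1k$values < 7.5))
})

test_that("attenuate_fricatives applies the strict > 7.5 rule exactly", {
  e <- rt_contour(c(0.4, 0.4, 0.4, 0.2), kind = "raw")
  z <- rt_contour(c(8, 7.5, 2, 9), kind = "zcr")
  out <- attenuate_fricatives(e, z)
  expect_equal(out$values, c(0.1, 0.4, 0.4, 0.05))

  voiced <- rt_contour(rep(3, 4), kind = "zcr")
  expect_equal(attenuate_fricatives(e, voiced)$values, e$values)

  short <- rt_contour(c(1, 2), kind = "zcr")
  expect_error(attenuate_fricatives(e, short), "frame grids")
  # attenuation never increases any frame
  expect_true(all(out$values <= e$values + 1e-15))
})

test_that("smooth_contour is zero-phase, mass-preserving, affine-exact", {
  const <- rt_contour(rep(2.5, 40), kind = "raw")
  expect_equal(smooth_contour(const, 6)$values, rep(2.5, 40))

  imp <- rt_contour(c(rep(0, 30), 1, rep(0, 30)), kind = "raw")
  sm <- smooth_contour(imp, 6)
  expect_equal(sum(sm$values), 1, tolerance = 1e-9)
  expect_equal(sum(sm$values > 0), 11L)  # spread over 2*6 - 1 frames
  # symmetric about the impulse -> no delay
  expect_equal(which.max(sm$values), 31L)

  ramp <- rt_contour(seq(0, 5, by = 0.1), kind = "raw")
  smr <- smooth_contour(ramp, 6)
  expect_equal(diff(smr$values)[10:40], rep(0.1, 31), tolerance = 1e-12)

  # matches the independent double-loop implementation on rough input
  set.seed(4)
  x <- abs(rnorm(120))
  expect_equal(smooth_contour(rt_contour(x, kind = "raw"), 6)$values,
               oracle_zero_phase_ma(x, 6), tolerance = 1e-12)
  expect_error(smooth_contour(const, 0), "positive integer")
})

test_that("energy_difference equals the manual E_T - E_{T-1} + MA oracle", {
  const <- rt_contour(rep(1, 30), kind = "smoothed")
  expect_true(all(abs(energy_difference(const)$values) < 1e-14))

  aff <- rt_contour(seq(1, 4, by = 0.05), kind = "smoothed")
  d <- energy_difference(aff)
  expect_equal(d$values[20:40], rep(0.05, 21), tolerance = 1e-12)

  x <- c(0.1, 0.3, 0.2, 0.9, 1.4, 1.3, 0.7, 0.6, 0.8, 0.2)
  got <- energy_difference(rt_contour(x, kind = "smoothed"), order = 10)
  manual <- oracle_zero_phase_ma(c(0, diff(x)), 10)
  expect_equal(got$values, manual, tolerance = 1e-12)

  expect_error(energy_difference(rt_contour(x, kind = "raw")), "smoothed")
})

test_that("find_maxD equals exhaustive argmax and honours the tie rule", {
  set.seed(7)
  for (i in 1:100) {
    v <- rnorm(200)
    d <- rt_contour(v, t0_s = 0, kind = "difference")
    a <- sort(runif(2, 0, 0.2))
    if (diff(a) < 0.005) next
    got <- find_maxD(d, a)
    want <- oracle_argmax(v, 0, a[1], a[2])
    expect_identical(got$time_s, want$time_s)
    expect_identical(got$value, want$value)
  }
  # plateau of equal maxima -> earliest frame
  v <- c(0, 1, 1, 1, 0)
  got <- find_maxD(rt_contour(v, kind = "difference"), c(0, 0.005))
  expect_equal(got$time_s, 0.001)
  expect_error(find_maxD(rt_contour(v, kind = "difference"), c(0.5, 0.6)),
               "overlap")
})

test_that("scaling the waveform scales energy by c^2, maxD unmoved", {
  set.seed(12)
  w <- synth_tone(0.4, 300, 0.03, 0.05, 0.5)
  w2 <- rt_wave(w$samples * 1.7, w$rate_hz)
  c1 <- energy_chain(w)
  c2 <- energy_chain(w2)
  expect_equal(c2$raw$values, c1$raw$values * 1.7^2, tolerance = 1e-9)
  syll <- c(0.01, 0.39)
  expect_identical(find_maxD(c2$difference, syll)$time_s,
                   find_maxD(c1$difference, syll)$time_s)
  # raw and smoothed energies nonnegative everywhere
  expect_true(all(c1$raw$values >= 0) && all(c1$smoothed$values >= 0))
})
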