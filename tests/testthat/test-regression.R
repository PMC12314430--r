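test_that("prepare_responses log-transforms on the ms scale", {
  tab <- data.frame(rise_time_ms = c(exp(3), 20, 30),
                    median_abs_ms = c(40, 50, 60),
                    median_signed_ms = c(-20, 0, 10))
  out <- prepare_responses(tab)
  expect_equal(out$log_rise_time_ms[1], 3.0)
  expect_equal(out$log_median_abs_ms, log(c(40, 50, 60)))
  # signed response untouched, no log column
  expect_null(out$log_median_signed_ms)
  expect_equal(out$median_signed_ms, tab$median_signed_ms)

  norm <- attr(out, "normality")
  expect_true(all(c("rise_time_ms", "median_abs_ms", "median_signed_ms")
                  %in% norm$response))

  tab$rise_time_ms[2] <- 0
  expect_error(prepare_responses(tab), "nonpositive.*2")

  # a large normal sample passes the normality check
  big <- data.frame(median_signed_ms = rnorm(400))
  W <- attr(prepare_responses(big), "normality")$W
  expect_gt(W, 0.98)
})

test_that("fit_lm matches closed-form OLS and reports the full table", {
  # exact line
  d <- data.frame(x = 1:6, y = 2 * (1:6) + 1)
  f <- suppressWarnings(fit_lm(d, "y", "x"))
  expect_equal(f$coefficients$b, c(1, 2), tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  expect_lt(max(f$coefficients$se), 1e-8)

  # hand linear algebra on a 5-row example
  d2 <- data.frame(x1 = c(1, 2, 3, 5, 8), x2 = c(0, 1, 0, 1, 1),
                   y = c(2.1, 3.9, 5.2, 9.8, 15.0))
  f2 <- fit_lm(d2, "y", c("x1", "x2"))
  X <- cbind(1, d2$x1, d2$x2)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d2$y)
  expect_equal(f2$coefficients$b, as.vector(beta_hat), tolerance = 1e-10)
  # CI = b +/- t_crit * SE
  tcrit <- qt(0.975, df = 2)
  expect_equal(f2$coefficients$ci_high - f2$coefficients$b,
               tcrit * f2$coefficients$se, tolerance = 1e-10)
  # standardized beta: b * sd(x)/sd(y); invariant to predictor rescaling
  d3 <- d2
  d3$x1 <- d3$x1 * 100
  f3 <- fit_lm(d3, "y", c("x1", "x2"))
  expect_equal(f3$coefficients$beta_std, f2$coefficients$beta_std,
               tolerance = 1e-10)
  expect_true(is.na(f2$coefficients$beta_std[1]))

  # reference coding: weak and onset complexity 0 are the references
  tab <- synth_feature_table(60, noise_sd = 0.3, seed = 2)
  fc <- fit_lm(tab, "y", c("weight", "onset_complexity"))
  expect_setequal(fc$coefficients$term,
                  c("(Intercept)", "weightstrong", "onset_complexity1",
                    "onset_complexity2"))

  # rank deficiency is an error naming the collinear column
  d4 <- data.frame(x1 = 1:8, x1b = 2 * (1:8), y = rnorm(8))
  expect_error(fit_lm(d4, "y", c("x1", "x1b")), "x1b")
  expect_error(fit_lm(d2[1:3, ], "y", c("x1", "x2")), "not enough")
})

test_that("backward_eliminate drops blocks and compares nested models", {
  set.seed(5)
  n <- 300
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n), junk = rnorm(n),
                    g = factor(sample(letters[1:3], n, replace = TRUE)))
  tab$y <- 2 * tab$x1 - 1.5 * tab$x2 + rnorm(n, 0, 0.5)
  full <- fit_lm(tab, "y", c("x1", "x2", "junk", "g"))
  be <- backward_eliminate(full)
  expect_setequal(be$final$terms, c("x1", "x2"))
  # factor g removed as a whole block
  expect_true("g" %in% be$dropped)
  expect_gte(be$comparison$F, 0)
  expect_equal(be$comparison$df1,
               length(coef(full$lm)) - length(coef(be$final$lm)))
  expect_gt(be$comparison$p, 0.05)
  # chi-square LRT reported alongside
  expect_gte(be$comparison$lrt_chisq, 0)

  # all terms significant: final = full, df1 = 0 edge case
  strong <- fit_lm(tab, "y", c("x1", "x2"))
  be2 <- backward_eliminate(strong)
  expect_identical(be2$final$terms, strong$terms)
  expect_equal(be2$comparison$df1, 0)
  expect_length(be2$dropped, 0L)
})

test_that("vif matches the closed form", {
  # empirically orthogonal predictors -> VIF exactly 1
  x1 <- rep(c(-1, 1), 20)
  x2 <- rep(c(-1, -1, 1, 1), 10)
  d <- data.frame(x1 = x1, x2 = x2)
  expect_equal(vif(d, c("x1", "x2"))$vif, c(1, 1), tolerance = 1e-12)

  # exact empirical correlation 0.8 -> VIF = 1/(1 - 0.64)
  set.seed(9)
  z1 <- rnorm(200)
  z2 <- rnorm(200)
  z2 <- residuals(lm(z2 ~ z1))
  z1 <- scale(z1)[, 1]
  z2 <- scale(z2)[, 1]
  d2 <- data.frame(a = z1, b = 0.8 * z1 + sqrt(1 - 0.64) * z2)
  v <- vif(d2, c("a", "b"))$vif
  expect_equal(v, rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  # duplicated column -> infinite VIF, flagged
  d3 <- data.frame(a = z1, b = z1)
  v3 <- vif(d3, c("a", "b"))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(all(v3$flagged))

  # factor expansion yields one VIF per dummy column
  tab <- synth_feature_table(80, noise_sd = 0.3, seed = 3)
  vf <- vif(tab, c("sonority", "onset_complexity"))
  expect_setequal(vf$column, c("sonority", "onset_complexity1",
                               "onset_complexity2"))
})

test_that("predictor_correlations flags only below the adjusted alpha", {
  set.seed(19)
  n <- 300
  d <- data.frame(a = rnorm(n))
  d$b <- d$a                         # identical
  d$c <- -d$a + rnorm(n, 0, 0.1)    # strongly anti-correlated
  d$e <- rnorm(n)                    # independent
  d$k <- rep(1, n)                   # constant
  pc <- predictor_correlations(d, alpha = 0.001)
  expect_equal(pc$r["a", "b"], 1)
  expect_true(pc$significant["a", "b"])
  expect_lt(pc$r["a", "c"], -0.9)
  expect_true(pc$significant["a", "c"])
  expect_false(pc$significant["a", "e"])
  expect_equal(pc$degenerate, "k")
  expect_true(all(is.na(pc$r["k", c("a", "b", "c", "e")])))
  expect_equal(pc$r, t(pc$r))  # symmetric by construction
})
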