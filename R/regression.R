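#' Prepare regression responses
#'
#' Natural-log transforms the duration-like responses (rise-time and median
#' absolute asynchrony, both right-skewed), leaves signed asynchrony raw,
#' and attaches a Shapiro-Wilk normality diagnostic for each response. Log
#' transforms are taken on the millisecond scale, so e.g. a 20-ms rise-time
#' maps to log(20) = 3.0.
#'
#' @param item_table Data frame holding the responses.
#' @param log_targets Character vector of columns to log-transform (default
#'   \code{c("rise_time_ms", "median_abs_ms")}; absent columns are ignored).
#' @param raw_targets Columns kept raw but still checked for normality
#'   (default \code{"median_signed_ms"}).
#' @return The table with added \code{log_<col>} columns and an attribute
#'   \code{"normality"}: data frame of response, W, p, transformed.
#' @export
prepare_responses <- function(item_table,
                              log_targets = c("rise_time_ms",
                                              "median_abs_ms"),
                              raw_targets = "median_signed_ms") {
  stopifnot(is.data.frame(item_table))
  log_targets <- intersect(log_targets, names(item_table))
  raw_targets <- intersect(raw_targets, names(item_table))
  checks <- list()
  for (col in log_targets) {
    v <- item_table[[col]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0L)
      stop("nonpositive values in `", col, "` at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    lv <- log(v)
    item_table[[paste0("log_", col)]] <- lv
    checks[[col]] <- shapiro_row(col, lv, transformed = TRUE)
  }
  for (col in raw_targets)
    checks[[col]] <- shapiro_row(col, item_table[[col]], transformed = FALSE)
  attr(item_table, "normality") <- do.call(rbind, unname(checks))
  item_table
}

shapiro_row <- function(name, v, transformed) {
  v <- v[is.finite(v)]
  if (length(v) >= 3L && length(v) <= 5000L && stats::sd(v) > 0) {
    sw <- stats::shapiro.test(v)
    data.frame(response = name, W = unname(sw$statistic),
               p = sw$p.value, transformed = transformed)
  } else {
    data.frame(response = name, W = NA_real_, p = NA_real_,
               transformed = transformed)
  }
}

#' Fit an ordinary least-squares model and tabulate it
#'
#' Fits \code{response ~ terms} by OLS with treatment (reference-level)
#' contrasts for factors, and assembles the coefficient table in the
#' conventional report layout: estimate b, SE, t, p, 95 percent confidence
#' interval, and post-hoc standardized coefficient
#' \code{beta_std = b * sd(x) / sd(y)} per (non-intercept) model-matrix
#' column.
#'
#' @param table Data frame with the response and predictor columns (no
#'   missing values among the used columns).
#' @param response Response column name.
#' @param terms Character vector of predictor column names.
#' @return Object of class \code{rt_fit}: list with \code{lm} (the fitted
#'   \code{lm}), \code{coefficients} (the tabulated terms), \code{response},
#'   \code{terms}, \code{n}, \code{F_stat}, \code{df1}, \code{df2},
#'   \code{r_squared}, \code{logLik}.
#' @export
fit_lm <- function(table, response, terms) {
  stopifnot(is.data.frame(table), length(terms) >= 0L)
  used <- c(response, terms)
  miss <- setdiff(used, names(table))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- table[, used, drop = FALSE]
  if (anyNA(dat))
    stop("missing values in the analysis table; apply exclusions first",
         call. = FALSE)
  if (nrow(dat) <= length(terms) + 1L)
    stop("not enough rows to fit the model", call. = FALSE)
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = dat)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  smry <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  sdy <- stats::sd(dat[[response]])
  co <- smry$coefficients
  beta <- vapply(rownames(co), function(nm) {
    if (nm == "(Intercept)") NA_real_
    else unname(co[nm, 1] * stats::sd(X[, nm]) / sdy)
  }, numeric(1))
  coefs <- data.frame(term = rownames(co), b = co[, 1], se = co[, 2],
                      t = co[, 3], p = co[, 4], ci_low = ci[, 1],
                      ci_high = ci[, 2], beta_std = beta,
                      row.names = NULL)
  fs <- smry$fstatistic
  structure(list(lm = fit, coefficients = coefs, response = response,
                 terms = terms, n = nrow(dat),
                 F_stat = if (is.null(fs)) NA_real_ else unname(fs[1]),
                 df1 = if (is.null(fs)) NA_real_ else unname(fs[2]),
                 df2 = if (is.null(fs)) NA_real_ else unname(fs[3]),
                 r_squared = smry$r.squared,
                 logLik = as.numeric(stats::logLik(fit))),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit: %s ~ %s, n = %d, R^2 = %.3f>\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
              x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Backward elimination with a final nested-model comparison
#'
#' Starting from the full model, repeatedly removes the least significant
#' term -- the one with the largest p-value at or above \code{alpha}, where
#' categorical factors are tested (and removed) as whole blocks via marginal
#' F-tests (\code{drop1}) -- and refits, until every remaining term is
#' significant. The final model is then compared against the full model with
#' a nested-model F-test; a chi-square likelihood-ratio test is reported
#' alongside.
#'
#' @param full An \code{rt_fit} for the fully specified model.
#' @param alpha Retention threshold (default 0.05).
#' @return List with \code{final} (an \code{rt_fit}), \code{comparison}
#'   (data frame: F, df1, df2, p, lrt_chisq, lrt_df, lrt_p), and
#'   \code{dropped} (terms in elimination order). When nothing is dropped
#'   the comparison has df1 = 0 and p = NA.
#' @export
backward_eliminate <- function(full, alpha = 0.05) {
  stopifnot(inherits(full, "rt_fit"))
  cur <- full
  dropped <- character(0)
  repeat {
    if (length(cur$terms) == 0L) break
    d1 <- stats::drop1(cur$lm, test = "F")
    pv <- d1[["Pr(>F)"]]
    names(pv) <- rownames(d1)
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0L || max(pv) < alpha) break
    worst <- names(pv)[which.max(pv)]
    dropped <- c(dropped, worst)
    cur <- fit_lm(full$lm$model, cur$response, setdiff(cur$terms, worst))
  }
  if (length(dropped) == 0L) {
    comparison <- data.frame(F = NA_real_, df1 = 0, df2 = full$n -
                               length(stats::coef(full$lm)),
                             p = NA_real_, lrt_chisq = 0, lrt_df = 0,
                             lrt_p = NA_real_)
  } else {
    an <- stats::anova(cur$lm, full$lm)
    rss0 <- an$RSS[1]; rss1 <- an$RSS[2]
    df1 <- an$Df[2]; df2 <- an$Res.Df[2]
    lrt <- full$n * log(rss0 / rss1)
    comparison <- data.frame(F = an$F[2], df1 = df1, df2 = df2,
                             p = an[["Pr(>F)"]][2], lrt_chisq = lrt,
                             lrt_df = df1,
                             lrt_p = stats::pchisq(lrt, df1,
                                                   lower.tail = FALSE))
  }
  list(final = cur, comparison = comparison, dropped = dropped)
}

#' Variance inflation factors
#'
#' VIF per column of the expanded (dummy-coded) model matrix:
#' \code{1 / (1 - R^2_j)} from regressing column j on the remaining
#' predictor columns. Perfectly collinear columns are reported as \code{Inf}
#' and flagged.
#'
#' @param table Data frame of predictors.
#' @param terms Character vector of predictor column names (>= 2 columns
#'   after expansion).
#' @return Data frame with \code{column}, \code{vif}, \code{flagged}.
#' @export
vif <- function(table, terms) {
  stopifnot(is.data.frame(table), length(terms) >= 2L)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = table)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2L)
    stop("need at least 2 predictor columns after expansion", call. = FALSE)
  out <- data.frame(column = colnames(X), vif = NA_real_, flagged = FALSE)
  for (j in seq_len(ncol(X))) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    y <- X[, j]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 > 1 - 1e-12) {
      out$vif[j] <- Inf
      out$flagged[j] <- TRUE
    } else {
      out$vif[j] <- 1 / (1 - r2)
    }
  }
  out
}

#' Pairwise predictor correlations with significance flags
#'
#' Pearson correlations among numeric predictors with per-pair p-values;
#' pairs are flagged significant only below the (multiple-test adjusted)
#' alpha, default 0.001. Constant columns give undefined correlations and
#' are flagged as degenerate.
#'
#' @param table Data frame of predictors.
#' @param terms Character vector of numeric predictor columns (default: all
#'   numeric columns).
#' @param alpha Significance threshold (default 0.001).
#' @return List with matrices \code{r}, \code{p}, logical
#'   \code{significant}, and character vector \code{degenerate} (constant
#'   columns).
#' @export
predictor_correlations <- function(table, terms = NULL, alpha = 0.001) {
  stopifnot(is.data.frame(table))
  if (is.null(terms))
    terms <- names(table)[vapply(table, is.numeric, logical(1))]
  X <- as.matrix(table[, terms, drop = FALSE])
  const <- terms[apply(X, 2, function(v) stats::sd(v) == 0)]
  k <- length(terms)
  r <- matrix(NA_real_, k, k, dimnames = list(terms, terms))
  p <- r
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (terms[i] %in% const || terms[j] %in% const) next
    ct <- stats::cor.test(X[, i], X[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  sig <- !is.na(p) & p < alpha
  diag(sig) <- FALSE
  list(r = r, p = p, significant = sig, degenerate = const)
}
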