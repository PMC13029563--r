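#' @title Method agreement statistics
#' @description Deming errors-in-variables regression with jackknife
#'   confidence intervals, Bland-Altman limits of agreement, mean
#'   predictive percent error (MPPE) / mean absolute percentage error
#'   (MAPE), and ANCOVA-based tests of calibration-slope heterogeneity.
#' @name method-comparison
NULL

#' Deming regression
#'
#' Errors-in-both-variables linear regression with error-variance ratio
#' `lambda` (= var(error in y) / var(error in x); 1 when replicate error
#' variances are unknown). The slope is the closed-form moment estimator;
#' 95% confidence intervals come from the leave-one-out jackknife with
#' t(n - 2) quantiles.
#'
#' @param x reference measurements.
#' @param y test measurements (same length, >= 3).
#' @param lambda error-variance ratio.
#' @param conf_level confidence level for the intervals.
#' @return Object of class `deming_fit`: list with `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `n`, `lambda`.
#' @examples
#' x <- c(1, 2, 3, 4, 5)
#' deming_regression(x, 2 * x + 1)$slope # 2
#' @export
deming_regression <- function(x, y, lambda = 1, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3, lambda > 0)
  if (stats::var(x) == 0) stop("all reference values identical")
  est <- deming_point(x, y, lambda)
  n <- length(x)
  # leave-one-out jackknife
  loo <- vapply(seq_len(n), function(i) {
    deming_point(x[-i], y[-i], lambda)
  }, numeric(2))
  ps <- n * est - (n - 1) * loo          # pseudo-values, 2 x n
  se <- apply(ps, 1, stats::sd) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  structure(list(
    slope = unname(est[1]), intercept = unname(est[2]),
    slope_ci = unname(est[1] + c(-1, 1) * tq * se[1]),
    intercept_ci = unname(est[2] + c(-1, 1) * tq * se[2]),
    n = n, lambda = lambda, conf_level = conf_level
  ), class = "deming_fit")
}

# Closed-form Deming point estimate (slope, intercept) via moment equations.
deming_point <- function(x, y, lambda) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sxy == 0 && syy == lambda * sxx) {
    return(c(slope = 1, intercept = my - mx))
  }
  b <- (syy - lambda * sxx + sqrt((syy - lambda * sxx)^2 +
                                    4 * lambda * sxy^2)) / (2 * sxy)
  c(slope = b, intercept = my - b * mx)
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "<deming_fit> slope %.4g (%g%% CI %.4g to %.4g), intercept %.4g (%.4g to %.4g), n = %d\n",
    x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$n))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `test - reference`, expressed in percent of the pairwise
#' mean by default (the deviation thresholds used for DBS agreement are
#' relative). The bias is the mean difference, the 95% limits of agreement
#' are `bias +/- 1.96 * SD(d)`, and the bias confidence interval uses the
#' t(n - 1) quantile.
#'
#' @param reference,test paired measurements (length >= 3).
#' @param mode `"percent_of_mean"` or `"absolute"`.
#' @param conf_level confidence level of the bias CI.
#' @return Object of class `bland_altman`: list with `bias`, `loa`
#'   (lower, upper), `bias_ci`, `sd_diff`, `differences`, `means`, `mode`.
#' @export
bland_altman <- function(reference, test,
                         mode = c("percent_of_mean", "absolute"),
                         conf_level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(length(reference) == length(test), length(reference) >= 3)
  m <- (reference + test) / 2
  d <- test - reference
  if (mode == "percent_of_mean") {
    if (any(m == 0)) stop("zero pairwise mean: percent difference undefined")
    d <- 100 * d / m
  }
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(bias = bias, loa = bias + c(-1, 1) * 1.96 * s,
                 bias_ci = bias + c(-1, 1) * tq * s / sqrt(n),
                 sd_diff = s, differences = d, means = m, mode = mode),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  unit <- if (x$mode == "percent_of_mean") "%" else ""
  cat(sprintf("<bland_altman> bias %.3g%s, 95%% LoA [%.3g, %.3g]%s\n",
              x$bias, unit, x$loa[1], x$loa[2], unit))
  invisible(x)
}

#' Mean predictive percent error and mean absolute percentage error
#'
#' `MPPE = 100/n * sum((test - ref)/ref)` and
#' `MAPE = 100/n * sum(|test - ref|/ref)`.
#'
#' @param reference,test paired measurements; references must be nonzero.
#' @return Named numeric: `mppe`, `mape` (percent).
#' @examples
#' predictive_errors(c(0.40, 0.40), c(0.42, 0.38)) # mppe 0, mape 5
#' @export
predictive_errors <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  if (any(reference == 0)) stop("zero reference value")
  e <- (test - reference) / reference
  c(mppe = 100 * mean(e), mape = 100 * mean(abs(e)))
}

#' ANCOVA test of calibration-slope heterogeneity
#'
#' Fits the full-interaction model `response ~ covariate * group` and
#' tests the covariate, group and interaction effects (Type III F tests
#' with sum-to-zero contrasts, as appropriate for the omnibus tests in
#' the presence of an interaction). Per-group slope differences versus
#' the reference group come from the treatment-coded fit's interaction
#' t statistics.
#'
#' @param data data.frame with the three columns below.
#' @param response,covariate,group column names.
#' @param reference_group level of `group` used as the slope reference.
#' @return Object of class `ancova_result`: list with `f_covariate`,
#'   `f_factor`, `f_interaction` (each: statistic, df1, df2, p), and
#'   `slope_contrasts` (data.frame: group, slope_diff, t, p vs reference).
#' @export
ancova_slopes <- function(data, response = "response",
                          covariate = "covariate", group = "group",
                          reference_group = NULL) {
  stopifnot(all(c(response, covariate, group) %in% names(data)))
  d <- data.frame(y = data[[response]], x = data[[covariate]],
                  g = factor(data[[group]]))
  if (nlevels(d$g) < 2) stop("need at least 2 groups")
  per_group_n <- table(d$g)
  if (any(per_group_n < 3)) stop("need at least 3 points per group")
  if (any(tapply(d$x, d$g, function(v) length(unique(v))) < 2)) {
    stop("singular design: a group has a constant covariate")
  }
  if (is.null(reference_group)) reference_group <- levels(d$g)[1]
  d$g <- stats::relevel(d$g, ref = as.character(reference_group))

  # Type III omnibus tests under sum-to-zero contrasts
  d_sum <- d
  stats::contrasts(d_sum$g) <- stats::contr.sum(nlevels(d_sum$g))
  fit_sum <- stats::lm(y ~ x * g, data = d_sum)
  rss <- sum(stats::resid(fit_sum)^2)
  sst <- sum((d$y - mean(d$y))^2)
  if (rss > .Machine$double.eps^0.5 * max(sst, 1)) {
    a3 <- car::Anova(fit_sum, type = 3)
    pick <- function(term) {
      i <- match(term, rownames(a3))
      list(statistic = a3[i, "F value"], df1 = a3[i, "Df"],
           df2 = a3["Residuals", "Df"], p = a3[i, "Pr(>F)"])
    }
  } else {
    # exact fit: no residual variance. A term with zero Type III sum of
    # squares carries no signal (F = 0, p = 1); one with positive SS is
    # infinitely significant.
    df2 <- stats::df.residual(fit_sum)
    pick <- function(term) {
      drop_formula <- switch(term, x = y ~ g + x:g, g = y ~ x + x:g,
                             "x:g" = y ~ x + g)
      fit_red <- stats::lm(drop_formula, data = d_sum)
      ss <- sum(stats::resid(fit_red)^2) - rss
      df1 <- stats::df.residual(fit_red) - df2
      if (ss <= .Machine$double.eps^0.5 * max(sst, 1)) {
        list(statistic = 0, df1 = df1, df2 = df2, p = 1)
      } else {
        list(statistic = Inf, df1 = df1, df2 = df2, p = 0)
      }
    }
  }

  # slope contrasts vs the reference under treatment coding
  fit_trt <- stats::lm(y ~ x * g, data = d)
  ct <- summary(fit_trt)$coefficients
  int_rows <- grep("^x:g", rownames(ct))
  contrasts_df <- data.frame(
    group = sub("^x:g", "", rownames(ct)[int_rows]),
    slope_diff = ct[int_rows, "Estimate"],
    t = ct[int_rows, "t value"],
    p = ct[int_rows, "Pr(>|t|)"],
    row.names = NULL
  )

  structure(list(f_covariate = pick("x"), f_factor = pick("g"),
                 f_interaction = pick("x:g"),
                 slope_contrasts = contrasts_df,
                 reference_group = as.character(reference_group)),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  fmt <- function(nm, f) {
    sprintf("  %-12s F(%d, %d) = %.2f, p = %.3g\n", nm, f$df1, f$df2,
            f$statistic, f$p)
  }
  cat("<ancova_result>\n", fmt("covariate", x$f_covariate),
      fmt("group", x$f_factor), fmt("interaction", x$f_interaction),
      sep = "")
  cat("  slope contrasts vs group", x$reference_group, ":\n")
  print(x$slope_contrasts, row.names = FALSE, digits = 3)
  invisible(x)
}
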