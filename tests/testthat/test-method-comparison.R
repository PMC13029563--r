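test_that("Deming regression recovers affine relationships exactly", {
  x <- c(1, 2.5, 4, 6, 9)
  f_id <- deming_regression(x, x)
  expect_equal(f_id$slope, 1, tolerance = 1e-12)
  expect_equal(f_id$intercept, 0, tolerance = 1e-12)
  f <- deming_regression(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_error(deming_regression(rep(2, 5), x), "identical")
})

test_that("Deming slopes are reciprocal when axes are swapped", {
  x <- c(1, 2, 4, 5, 7, 10)
  y <- 1.8 * x + 0.6
  expect_equal(deming_regression(x, y)$slope * deming_regression(y, x)$slope,
               1, tolerance = 1e-10)
})

test_that("Deming jackknife CI covers the generating slope at ~95%", {
  set.seed(99)
  cover <- mean(vapply(seq_len(500), function(i) {
    x <- runif(15, 1, 10)
    xo <- x + rnorm(15, 0, 0.5)
    yo <- 1.5 * x + 2 + rnorm(15, 0, 0.5)
    f <- deming_regression(xo, yo)
    f$slope_ci[1] <= 1.5 && 1.5 <= f$slope_ci[2]
  }, logical(1)))
  expect_gte(cover, 0.93)
})

test_that("Bland-Altman of a series against itself is all zero", {
  x <- c(10, 12, 15, 18)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(0, 0))
})

test_that("Bland-Altman uses mean, 1.96 SD limits, and t-based bias CI", {
  ref <- c(100, 100, 100, 100)
  test <- c(110, 90, 110, 90)
  ba <- bland_altman(ref, test, mode = "absolute")
  d <- test - ref
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa, mean(d) + c(-1, 1) * 1.96 * sd(d))
  expect_equal(ba$bias_ci,
               mean(d) + c(-1, 1) * qt(0.975, 3) * sd(d) / 2)
  # absolute-mode bias is exactly the difference of means
  expect_equal(ba$bias, mean(test) - mean(ref))
  # percent mode divides by the pairwise means
  bp <- bland_altman(ref, test)
  expect_equal(bp$differences, 100 * d / ((ref + test) / 2))
  expect_error(bland_altman(c(1, -1, 2), c(-1, 1, 2)), "zero pairwise mean")
})

test_that("image-method HCT agrees with the reference within 20% in cohorts", {
  # replicated synthetic cohorts at printed image-method noise
  model <- mgv_model()
  ok <- vapply(seq_len(60), function(i) {
    co <- generate_patient_cohort(n = 23, seed = 7000 + i)
    est <- estimate_hct(model, co$mgv)$hct
    d <- 100 * (est - co$reference_hct) / ((est + co$reference_hct) / 2)
    all(abs(d) < 20)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("MPPE and MAPE match hand arithmetic", {
  expect_equal(predictive_errors(c(1, 2, 3), c(1, 2, 3)),
               c(mppe = 0, mape = 0))
  expect_equal(predictive_errors(c(0.40, 0.40), c(0.42, 0.38)),
               c(mppe = 0, mape = 5), tolerance = 1e-12)
  r <- c(2, 5, 9)
  expect_equal(predictive_errors(r, 1.05 * r),
               c(mppe = 5, mape = 5), tolerance = 1e-12)
  expect_error(predictive_errors(c(0, 1), c(1, 1)), "zero reference")
})

test_that("MAPE dominates |MPPE|, with equality only for one-signed errors", {
  set.seed(4)
  for (i in 1:25) {
    ref <- runif(12, 0.3, 0.5)
    test <- ref * (1 + rnorm(12, 0, 0.1))
    pe <- predictive_errors(ref, test)
    expect_gte(pe[["mape"]], abs(pe[["mppe"]]) - 1e-12)
  }
  one_signed <- predictive_errors(c(1, 2, 4), c(1.1, 2.3, 4.2))
  expect_equal(one_signed[["mape"]], one_signed[["mppe"]])
})

test_that("ANCOVA reproduces the published design's df structure", {
  set.seed(21)
  d <- slope_design() # 5 HCT groups x 5 volumes x 6 replicates
  a <- ancova_slopes(d, "y", "x", "group")
  expect_equal(a$f_interaction$df1, 4)
  expect_equal(a$f_interaction$df2, 140)
  expect_equal(a$f_covariate$df1, 1)
  expect_equal(nrow(a$slope_contrasts), 4)
})

test_that("noise-free equal slopes give zero interaction contrasts", {
  d <- slope_design(sd = 0)
  a <- suppressWarnings(ancova_slopes(d, "y", "x", "group"))
  expect_equal(a$slope_contrasts$slope_diff, rep(0, 4), tolerance = 1e-10)
  expect_equal(a$f_interaction$statistic, 0)
  expect_equal(a$f_interaction$p, 1)
})

test_that("ANCOVA detects genuinely different slopes", {
  set.seed(31)
  d <- slope_design(slopes = c(25.97, 26.06, 25.18, 23.01, 23.22), sd = 1)
  a <- ancova_slopes(d, "y", "x", "group", reference_group = 1)
  expect_lt(a$f_interaction$p, 0.001)
  # the 0.5/0.6-level slopes differ from the 0.2 reference
  expect_lt(a$slope_contrasts$p[a$slope_contrasts$group == "4"], 0.001)
  expect_lt(a$slope_contrasts$p[a$slope_contrasts$group == "5"], 0.01)
})

test_that("ANCOVA interaction test holds its nominal type-I error", {
  set.seed(123)
  rej <- mean(vapply(seq_len(1000), function(i) {
    d <- slope_design(sd = 5)
    ancova_slopes(d, "y", "x", "group")$f_interaction$p < 0.05
  }, logical(1)))
  expect_gte(rej, 0.05 - 0.016)
  expect_lte(rej, 0.05 + 0.016)
})

test_that("ANCOVA rejects degenerate designs", {
  d <- slope_design()
  d1 <- d[d$group == 1, ]
  expect_error(ancova_slopes(d1, "y", "x", "group"), "at least 2 groups")
  d$x[d$group == 2] <- 7
  expect_error(ancova_slopes(d, "y", "x", "group"), "singular")
})
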