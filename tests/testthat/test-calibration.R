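test_that("fits recover the published coefficients from noise-free points", {
  h <- seq(0.2, 0.6, by = 0.1)
  f_abs <- fit_calibration(h, 1.137 * h + 0.003, "linear")
  expect_equal(f_abs$coefficients, c(1.137, 0.003), tolerance = 1e-9)
  expect_equal(f_abs$r2, 1, tolerance = 1e-12)
  expect_equal(f_abs$range, c(0.2, 0.6))

  f_mgv <- fit_calibration(h, 161.67 * h^2 - 237.12 * h + 177.64,
                           "quadratic")
  expect_equal(f_mgv$coefficients, c(161.67, -237.12, 177.64),
               tolerance = 1e-7)
  expect_equal(f_mgv$r2, 1, tolerance = 1e-12)
})

test_that("degenerate and deficient designs are handled", {
  h <- seq(0.2, 0.6, by = 0.1)
  f <- fit_calibration(h, rep(3, 5), "linear")
  expect_equal(f$coefficients[1], 0)
  expect_equal(f$r2, 0)
  expect_error(fit_calibration(c(1, 2), c(1, 2), "linear"), "at least")
  expect_error(fit_calibration(rep(1, 5), 1:5, "linear"), "rank-deficient")
})

test_that("inversion matches hand-computed values", {
  expect_equal(as.numeric(invert_calibration(abs_model(), 0.003)), 0)
  m <- mgv_model()
  # smaller quadratic root at the forward values of HCT 0.2 and 0.6
  r02 <- (237.12 - sqrt(237.12^2 - 4 * 161.67 * (177.64 - 136.68))) /
    (2 * 161.67)
  expect_equal(as.numeric(invert_calibration(m, 136.68)), r02)
  expect_equal(as.numeric(invert_calibration(m, 136.68)), 0.200,
               tolerance = 1e-4)
  expect_equal(as.numeric(invert_calibration(m, 93.57)), 0.600,
               tolerance = 1e-4)
})

test_that("round trip invert(predict(x)) = x to 6 significant digits", {
  for (x in seq(0.2, 0.6, by = 0.02)) {
    lin <- abs_model()
    expect_equal(as.numeric(invert_calibration(lin, predict(lin, x))), x,
                 tolerance = 1e-7)
    quad <- mgv_model()
    expect_equal(as.numeric(invert_calibration(quad, predict(quad, x))), x,
                 tolerance = 1e-7)
  }
})

test_that("quadratic inversion stays on the monotone-decreasing branch", {
  m <- mgv_model()
  ys <- seq(predict(m, 0.6), predict(m, 0.2), length.out = 25)
  xs <- vapply(ys, function(y) as.numeric(invert_calibration(m, y)),
               numeric(1))
  expect_true(all(diff(xs) < 0)) # larger response -> smaller HCT
  vertex <- 237.12 / (2 * 161.67)
  expect_true(all(xs <= vertex))
})

test_that("inversion flags and errors behave as specified", {
  m <- mgv_model()
  oor <- invert_calibration(m, predict(m, 0.1))
  expect_true(attr(oor, "out_of_range"))
  inr <- invert_calibration(m, predict(m, 0.4))
  expect_false(attr(inr, "out_of_range"))
  # below the parabola minimum: error unless clipped to the vertex
  expect_error(invert_calibration(m, 80), "complex")
  clipped <- invert_calibration(m, 80, clip = TRUE)
  expect_equal(as.numeric(clipped), 237.12 / (2 * 161.67))
  expect_error(invert_calibration(calibration_model(c(0, 5)), 1),
               "zero-slope")
})

test_that("QC accuracy and RSD use the bioanalytical conventions", {
  # identity model so back-calculated values equal responses
  ident <- calibration_model(c(1, 0), range = c(0, 1))
  rep3 <- data.frame(level = 0.40, replicate = 1:3,
                     response = c(0.38, 0.40, 0.42))
  cal <- data.frame(level = c(0.2, 0.4, 0.6),
                    response = c(0.2, 0.4, 0.6))
  v <- validate_calibration(ident, cal, rep3)
  expect_equal(v$qc$accuracy_pct, 100)
  expect_equal(v$qc$rsd_pct, 100 * sd(c(0.38, 0.40, 0.42)) / 0.40)
  expect_equal(v$qc$rsd_pct, 5.0, tolerance = 1e-10)
  expect_true(v$pass)
})

test_that("noise-free calibrators validate with zero deviation", {
  m <- dbs_models()
  cal <- generate_calibrators(noise = zero_noise, seed = 1)
  d <- cal[cal$modality == "abs", ]
  f <- fit_calibration(d$level, d$response, "linear")
  qc <- data.frame(level = rep(c(0.2, 0.4, 0.6), each = 2),
                   response = model_response(m, "abs",
                                             rep(c(0.2, 0.4, 0.6), each = 2)))
  v <- validate_calibration(f, d[, c("level", "response")], qc)
  expect_true(v$pass)
  expect_equal(v$calibrator$deviation_pct, rep(0, 5), tolerance = 1e-9)
  expect_equal(v$lloq_level, 0.2)
  expect_equal(v$calibrator$tolerance_pct, c(20, 15, 15, 15, 15))
})

test_that("an out-of-window QC level fails validation and is identified", {
  ident <- calibration_model(c(1, 0), range = c(0, 1))
  cal <- data.frame(level = c(0.2, 0.4, 0.6), response = c(0.2, 0.4, 0.6))
  qc <- data.frame(level = rep(c(0.2, 0.4), each = 3),
                   response = c(0.2, 0.2, 0.2,       # accuracy 100
                                0.336, 0.336, 0.336)) # accuracy 84
  v <- validate_calibration(ident, cal, qc)
  expect_false(v$pass)
  expect_false(v$qc$pass[v$qc$level == 0.4])
  expect_true(v$qc$pass[v$qc$level == 0.2])
  expect_equal(v$qc$accuracy_pct[v$qc$level == 0.4], 84)
})

test_that("fitted slopes from noisy calibrators are unbiased", {
  # 500 replicates of the five-donor absorbance design at printed noise
  slopes <- vapply(seq_len(500), function(i) {
    cal <- generate_calibrators(modalities = "abs", seed = 1000 + i)
    fit_calibration(cal$level, cal$response, "linear")$coefficients[1]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.137) / 1.137, 0.01)
})
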