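test_that("noise-free calibrators lie exactly on the generating models", {
  cal <- generate_calibrators(noise = zero_noise, seed = 1)
  m <- dbs_models()
  for (mod in c("mgv", "sa", "abs")) {
    d <- cal[cal$modality == mod, ]
    expect_equal(d$response, model_response(m, mod, d$level),
                 tolerance = 1e-15)
  }
  # hand value: absorbance line at HCT 0.4
  abs04 <- cal$response[cal$modality == "abs" & cal$level == 0.4]
  expect_equal(abs04, rep(1.137 * 0.4 + 0.003, 5))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_calibrators(seed = 42)
  b <- generate_calibrators(seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_calibrators(seed = 43)))

  ca <- suppressWarnings(generate_conductivity_table(
    noise = noise_spec(100, 5), seed = 9))
  cb <- suppressWarnings(generate_conductivity_table(
    noise = noise_spec(100, 5), seed = 9))
  expect_identical(ca, cb)

  ia <- generate_spot_image(0.35, image_noise_sd = 3, seed = 5)
  ib <- generate_spot_image(0.35, image_noise_sd = 3, seed = 5)
  expect_identical(ia$pixels, ib$pixels)

  pa <- generate_patient_cohort(n = 10, seed = 3)
  pb <- generate_patient_cohort(n = 10, seed = 3)
  expect_identical(pa, pb)
})

test_that("modality substreams are independent of each other's settings", {
  base <- generate_calibrators(seed = 7)
  # perturbing the sa noise must not change the abs or mgv draws
  pert <- generate_calibrators(
    noise = list(mgv = "qc", abs = "qc", sa = noise_spec(100, 25)),
    seed = 7)
  expect_identical(base[base$modality == "abs", ],
                   pert[pert$modality == "abs", ])
  expect_identical(base[base$modality == "mgv", ],
                   pert[pert$modality == "mgv", ])
  expect_false(identical(base[base$modality == "sa", "response"],
                         pert[pert$modality == "sa", "response"]))
})

test_that("calibration refit on noise-free calibrators recovers coefficients", {
  cal <- generate_calibrators(noise = zero_noise, seed = 1)
  m <- dbs_models()
  d <- cal[cal$modality == "mgv", ]
  f <- fit_calibration(d$level, d$response, "quadratic")
  expect_equal(f$coefficients, m$mgv, tolerance = 1e-7)
  d <- cal[cal$modality == "abs", ]
  f <- fit_calibration(d$level, d$response, "linear")
  expect_equal(f$coefficients, m$abs, tolerance = 1e-7)
})

test_that("calibrator generation rejects bad inputs", {
  expect_error(generate_calibrators(hct_levels = numeric(0)), "empty")
  expect_error(generate_calibrators(modalities = "raman"),
               "unknown modality")
})

test_that("conductivity table follows the printed per-HCT line algebra", {
  tbl <- generate_conductivity_table(volumes = 20, hct_levels = 0.4,
                                     n_replicates = 1, seed = 1)
  expect_equal(tbl$conductivity, (20 - (-0.01)) / 25.18)
  expect_equal(tbl$conductivity, 0.7947, tolerance = 1e-4)

  # one-slope-above-intercept identity at HCT 0.2
  tbl2 <- generate_conductivity_table(volumes = 10.19 + 25.97,
                                      hct_levels = 0.2, n_replicates = 1,
                                      seed = 1)
  expect_equal(tbl2$conductivity, 1.0)
})

test_that("sub-intercept volumes give negative conductivity with a warning", {
  expect_warning(
    tbl <- generate_conductivity_table(volumes = 5, hct_levels = 0.5,
                                       n_replicates = 1, seed = 1),
    "negative conductivity")
  expect_lt(tbl$conductivity, 0)
  expect_equal(tbl$conductivity, (5 - 29.78) / 23.01)
})

test_that("conductivity table validates its inputs", {
  expect_error(generate_conductivity_table(volumes = 3), "5-40")
  expect_error(generate_conductivity_table(hct_levels = 0.45),
               "no conductivity line")
})

test_that("patient cohort respects the HCT range and truth models", {
  co <- generate_patient_cohort(n = 23, hct_range = c(0.35, 0.46), seed = 11)
  expect_equal(nrow(co), 23)
  expect_true(all(co$true_hct >= 0.35 & co$true_hct <= 0.46))
  # punch volume truth at the tabulated anchor
  expect_equal(punch_volume(dbs_models(), 0.4), 9.6)
  expect_equal(co$true_punch_volume,
               punch_volume(dbs_models(), co$true_hct))
})

test_that("zero-noise cohort reproduces the truth in every column", {
  zero <- list(mgv = zero_noise, abs = zero_noise, cond = zero_noise,
               reference = zero_noise)
  co <- generate_patient_cohort(n = 8, noise = zero, seed = 2)
  m <- dbs_models()
  expect_equal(co$reference_hct, co$true_hct)
  expect_equal(co$mgv, model_response(m, "mgv", co$true_hct))
  expect_equal(co$abs550, model_response(m, "abs", co$true_hct))
  # average-curve conductivity truth inverts back to the punch volume
  expect_equal(m$cond_pooled[1] * co$conductivity + m$cond_pooled[2],
               co$true_punch_volume)
  expect_error(generate_patient_cohort(n = 0), "positive")
})
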