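test_that("the decision rules map sample metadata to strategies", {
  # volumetric sample from a typical-HCT population: nothing to correct
  d <- decide_workflow(volumetric = TRUE, hct_known = TRUE,
                       population_hct = 0.40)
  expect_equal(d$strategy, "none")
  expect_equal(d$hct_method, "none")

  # scan and conductivity available, HCT unknown, non-volumetric
  d2 <- decide_workflow(volumetric = FALSE, hct_known = FALSE,
                        has_scan = TRUE, has_conductivity = TRUE)
  expect_equal(d2$hct_method, "image")
  expect_equal(d2$volume_method, "conductivity")
  expect_equal(d2$strategy, "both")

  # hemoglobin fallback when no scan exists
  d3 <- decide_workflow(volumetric = FALSE, hct_known = FALSE,
                        has_hb = TRUE, has_conductivity = TRUE)
  expect_equal(d3$hct_method, "hb")

  # known HCT but unknown volume: conductivity is required
  d4 <- decide_workflow(volumetric = FALSE, hct_known = TRUE,
                        has_conductivity = TRUE)
  expect_equal(d4$strategy, "both")
  expect_equal(d4$volume_method, "conductivity")

  expect_error(decide_workflow(volumetric = FALSE, hct_known = TRUE),
               "volume modality")
  expect_error(decide_workflow(volumetric = FALSE, hct_known = FALSE,
                               has_conductivity = TRUE),
               "no HCT modality")
})

test_that("the pipeline runs end to end and is bitwise reproducible", {
  out1 <- file.path(withr::local_tempdir(), "run1")
  out2 <- file.path(withr::local_tempdir(), "run2")
  res1 <- suppressWarnings(run_pipeline(list(seed = 7, n_draws = 2000), out1))
  res2 <- suppressWarnings(run_pipeline(list(seed = 7, n_draws = 2000), out2))

  expected <- c("config.yml", "models.json", "validation.json", "cohort.csv",
                "estimates.csv", "corrected.csv", "comparison.json",
                "error_grid.csv", "pipeline.log")
  expect_true(all(expected %in% list.files(out1)))
  expect_true(all(sapply(res1$validation, `[[`, "pass")))

  for (f in setdiff(expected, "pipeline.log")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  expect_error(run_pipeline(list(n_patients = 5), withr::local_tempdir()),
               "seed")
})

test_that("the pipeline accepts a YAML config file", {
  cfg_path <- file.path(withr::local_tempdir(), "cfg.yml")
  yaml::write_yaml(list(seed = 3, n_patients = 6, n_draws = 500), cfg_path)
  res <- suppressWarnings(run_pipeline(cfg_path, withr::local_tempdir()))
  expect_equal(nrow(res$cohort), 6)
  expect_equal(res$config$seed, 3)
  # the bundled demo config carries the mandatory seed
  demo <- yaml::read_yaml(system.file("extdata", "demo_config.yml",
                                      package = "dbsbias"))
  expect_true(is.numeric(demo$seed))
})

test_that("corrected plasma concentrations track truth across a large cohort", {
  # 500-patient synthetic cohort, full correction, K = 1: the recovered
  # plasma concentrations should fall inside the Monte Carlo 95% band of
  # the matching scenario for at least 93% of samples
  # cohort noise fixed at the medium-QC values — the level the nearest-QC
  # rule selects for every HCT in 0.35-0.46 — so that the Monte Carlo band
  # describes the same measurement quality the cohort was generated with
  models <- dbs_models()
  co <- generate_patient_cohort(
    n = 500, seed = 77,
    noise = list(mgv = "qc", abs = noise_spec(100, 7.44),
                 cond = noise_spec(100, 5.57),
                 reference = noise_spec(100, 0)))
  abs_fit <- abs_model()
  hct_est <- estimate_hct(abs_fit, co$abs550)$hct
  curves <- conductivity_curves(models)
  vol_est <- estimate_volume(co$conductivity, curves, policy = "average")

  vnom <- punch_volume(models, 0.4)
  k <- 1
  cb_obs <- (1 - co$true_hct + k * co$true_hct) * co$true_punch_volume / vnom
  cp <- plasma_concentration(cb_obs, hct_est, k,
                             vpred = vol_est$volume, vnom = vnom)
  rel_err <- 100 * (cp - 1)

  band <- simulate_relative_error(
    mc_scenario(0.4, k, strategy = "both", n_draws = 5e4, seed = 78))
  inside <- rel_err >= band$p2_5 & rel_err <= band$p97_5
  expect_gte(mean(inside), 0.93)
})
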