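#' @title Correction decision workflow and end-to-end pipeline
#' @description Encodes the DBS analysis decision workflow — which HCT and
#'   volume methods to use and which correction strategy to apply for a
#'   given sample — and an end-to-end, seeded pipeline over synthetic data
#'   that produces calibrations, estimates, corrected concentrations,
#'   agreement reports and the Monte Carlo error grid in one run directory.
#' @name workflow
NULL

#' Decide the correction workflow for a sample
#'
#' Deterministic rule table:
#' * volumetric spotting and a known population HCT inside `band`
#'   (calibrators matched at HCT 0.4): no correction needed;
#' * HCT known but punch volume unknown: correct HCT only, measure volume
#'   by conductivity when a volume estimate is still wanted;
#' * both unknown: correct both, estimating HCT from the scan when one
#'   exists (image method) and from hemoglobin absorbance otherwise, and
#'   volume from conductivity.
#'
#' @param volumetric was the blood spotted volumetrically?
#' @param hct_known is a reference HCT available?
#' @param population_hct known/assumed population HCT (fraction), or `NA`.
#' @param has_scan,has_hb,has_conductivity available measurement modalities.
#' @param band HCT band in which the average-curve/no-correction shortcut
#'   applies.
#' @return Object of class `workflow_decision`: list with `sample_kind`,
#'   `hct_known`, `hct_method` (`"image"`, `"hb"`, `"none"`),
#'   `volume_method` (`"conductivity"`, `"reference"`, `"none"`) and
#'   `strategy` (as in [mc_scenario()]).
#' @examples
#' decide_workflow(volumetric = TRUE, hct_known = TRUE, population_hct = 0.40)
#' @export
decide_workflow <- function(volumetric, hct_known, population_hct = NA,
                            has_scan = FALSE, has_hb = FALSE,
                            has_conductivity = FALSE,
                            band = c(0.35, 0.46)) {
  stopifnot(is.logical(volumetric), is.logical(hct_known))
  hct_in_band <- !is.na(population_hct) &&
    population_hct >= band[1] && population_hct <= band[2]

  if (volumetric && hct_known && hct_in_band) {
    dec <- list(hct_method = "none", volume_method = "none",
                strategy = "none")
  } else if (hct_known) {
    if (!volumetric && !has_conductivity) {
      stop("non-volumetric sample with unknown volume: ",
           "a volume modality (conductivity) is required")
    }
    dec <- list(hct_method = "none",
                volume_method = if (volumetric) "none" else "conductivity",
                strategy = if (volumetric) "hct_only" else "both")
  } else {
    hct_method <- if (has_scan) "image" else if (has_hb) "hb" else
      stop("HCT unknown and no HCT modality (scan or hemoglobin) available")
    if (volumetric) {
      dec <- list(hct_method = hct_method, volume_method = "none",
                  strategy = "hct_only")
    } else {
      if (!has_conductivity) {
        stop("non-volumetric sample with unknown volume: ",
             "a volume modality (conductivity) is required")
      }
      dec <- list(hct_method = hct_method, volume_method = "conductivity",
                  strategy = "both")
    }
  }
  structure(c(list(sample_kind = if (volumetric) "volumetric" else
                     "non-volumetric",
                   hct_known = hct_known), dec),
            class = "workflow_decision")
}

#' @export
print.workflow_decision <- function(x, ...) {
  cat(sprintf("<workflow_decision> %s sample, HCT %s: hct_method=%s, volume_method=%s, strategy=%s\n",
              x$sample_kind, if (x$hct_known) "known" else "unknown",
              x$hct_method, x$volume_method, x$strategy))
  invisible(x)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates calibrators/QCs and a patient cohort, fits and validates all
#' calibrations, estimates HCT and punch volume for every patient,
#' corrects a unit plasma concentration for each, runs the method
#' agreement analyses and the Monte Carlo error grid, and writes every
#' result (CSV/JSON), a structured log and the seeded config (with its
#' hash) into `out_dir`. Re-running with the same config reproduces every
#' number bit for bit.
#'
#' @param config named list (or path to a YAML file) with at least `seed`;
#'   optional entries `n_patients`, `hct_range`, `k`, `n_draws`,
#'   `curve_policy`, `band`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `calibrations`,
#'   `validation`, `cohort`, `estimates`, `corrected`, `comparison`,
#'   `error_grid`, `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must specify a seed")
  cfg <- utils::modifyList(list(n_patients = 23, hct_range = c(0.35, 0.46),
                                k = 1, n_draws = 1e4,
                                curve_policy = "auto",
                                band = c(0.35, 0.46)),
                           config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- config_hash(cfg)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", cfg_hash, stage, msg),
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  yaml::write_yaml(c(cfg, list(config_hash = cfg_hash)),
                   file.path(out_dir, "config.yml"))
  models <- dbs_models()
  seed <- cfg$seed

  # calibration stage
  cal <- generate_calibrators(seed = seed)
  qc <- lapply(c(mgv = "mgv", sa = "sa", abs = "abs"), function(m) {
    generate_qc(modality = m, seed = seed)
  })
  fits <- list(
    mgv = fit_calibration(cal$level[cal$modality == "mgv"],
                          cal$response[cal$modality == "mgv"], "quadratic",
                          "HCT", "MGV"),
    sa = fit_calibration(cal$level[cal$modality == "sa"],
                         cal$response[cal$modality == "sa"], "linear",
                         "HCT", "SA"),
    abs = fit_calibration(cal$level[cal$modality == "abs"],
                          cal$response[cal$modality == "abs"], "linear",
                          "HCT", "ABS")
  )
  validation <- lapply(names(fits), function(m) {
    v <- validate_calibration(fits[[m]],
                              cal[cal$modality == m,
                                  c("level", "response")], qc[[m]])
    list(method = m, pass = v$pass, calibrator = v$calibrator, qc = v$qc)
  })
  names(validation) <- names(fits)
  jsonlite::write_json(
    lapply(fits, function(f) f[c("kind", "coefficients", "range", "r2")]),
    file.path(out_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(validation, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logf("calibrate", sprintf("%d calibrator rows in, %d models out",
                            nrow(cal), length(fits)))

  cond_tbl <- generate_conductivity_table(models, seed = seed)
  curves_fit <- fit_conductivity_curves(cond_tbl)
  # patient estimation uses the validated (published) curves; the refit
  # above documents that the calibration experiment recovers them
  curves <- conductivity_curves(models)
  logf("conductivity", sprintf("%d rows in, %d curves out", nrow(cond_tbl),
                               length(curves$per_hct) + 1L))

  # estimation stage
  cohort <- generate_patient_cohort(cfg$n_patients, cfg$hct_range,
                                    models, seed = seed)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  hct_hb <- estimate_hct(fits$abs, cohort$abs550)
  vol <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    estimate_volume(cohort$conductivity[i], curves,
                    hct_estimate = hct_hb$hct[i],
                    policy = cfg$curve_policy, band = cfg$band)
  }))
  estimates <- data.frame(patient = cohort$patient,
                          hct_est = hct_hb$hct,
                          hct_out_of_range = hct_hb$out_of_range,
                          volume_est = vol$volume,
                          curve_used = vol$curve_used,
                          negative_conductivity = vol$negative_conductivity)
  utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  logf("estimate", sprintf("%d patients in, %d estimates out",
                           nrow(cohort), nrow(estimates)))

  # correction stage: unit true plasma concentration, observed Cb per the
  # partition model and the patient's true punch volume
  vnom <- punch_volume(models, 0.4)
  cb_obs <- (1 - cohort$true_hct + cfg$k * cohort$true_hct) *
    cohort$true_punch_volume / vnom
  corrected <- data.frame(
    patient = cohort$patient,
    cb = cb_obs,
    cp_true = 1,
    cp_est = plasma_concentration(cb_obs, estimates$hct_est, cfg$k,
                                  vpred = estimates$volume_est, vnom = vnom)
  )
  corrected$rel_err_pct <- 100 * (corrected$cp_est - corrected$cp_true)
  utils::write.csv(corrected, file.path(out_dir, "corrected.csv"),
                   row.names = FALSE)
  logf("correct", sprintf("%d samples corrected", nrow(corrected)))

  # agreement stage
  comparison <- list(
    hct_hb_vs_reference = unclass(deming_regression(cohort$reference_hct,
                                                    hct_hb$hct)),
    hct_hb_bland_altman = unclass(bland_altman(cohort$reference_hct,
                                               hct_hb$hct))[
      c("bias", "loa", "bias_ci", "mode")],
    hct_hb_errors = as.list(predictive_errors(cohort$reference_hct,
                                              hct_hb$hct)),
    volume_vs_reference = as.list(predictive_errors(
      reference_volume(cohort$true_hct), estimates$volume_est))
  )
  jsonlite::write_json(comparison, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  logf("compare", "agreement reports written")

  grid <- run_error_grid(n_draws = cfg$n_draws, seed = seed, models = models)
  utils::write.csv(grid, file.path(out_dir, "error_grid.csv"),
                   row.names = FALSE)
  logf("error-grid", sprintf("%d cells", nrow(grid)))

  invisible(list(calibrations = fits, validation = validation,
                 curves = curves, curves_fit = curves_fit,
                 cohort = cohort, estimates = estimates,
                 corrected = corrected, comparison = comparison,
                 error_grid = grid, config = cfg))
}

# Stable short hash of a config list (over its deparsed canonical form).
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)))
}
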