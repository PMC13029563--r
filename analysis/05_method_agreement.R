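#!/usr/bin/env Rscript
# Agreement of the estimation methods with their references on the synthetic
# patient cohort: Deming regression, Bland-Altman, MPPE/MAPE for the image
# and hemoglobin HCT methods against the reference HCT, and for the
# conductivity punch volume against the surface-area reference model.

suppressPackageStartupMessages(library(dbsbias))
data_dir <- "results/data"
out <- "results/agreement"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- read.csv(file.path(data_dir, "cohort.csv"))
models <- jsonlite::read_json("results/calibration/models.json",
                              simplifyVector = TRUE)
as_model <- function(m, resp) calibration_model(m$coefficients,
                                                range = m$range, r2 = m$r2,
                                                response_name = resp)

report <- function(label, ref, test) {
  dm <- deming_regression(ref, test)
  ba <- bland_altman(ref, test)
  pe <- predictive_errors(ref, test)
  cat(sprintf("%s:\n  Deming slope %.2f (95%% CI %.2f to %.2f), intercept %.3f (%.3f to %.3f)\n",
              label, dm$slope, dm$slope_ci[1], dm$slope_ci[2],
              dm$intercept, dm$intercept_ci[1], dm$intercept_ci[2]))
  cat(sprintf("  Bland-Altman bias %.2f%%, 95%% LoA [%.2f, %.2f]%%; max |d| %.2f%%\n",
              ba$bias, ba$loa[1], ba$loa[2], max(abs(ba$differences))))
  cat(sprintf("  MPPE %.2f%%, MAPE %.2f%%\n", pe["mppe"], pe["mape"]))
  data.frame(comparison = label, deming_slope = dm$slope,
             slope_lo = dm$slope_ci[1], slope_hi = dm$slope_ci[2],
             deming_intercept = dm$intercept, ba_bias_pct = ba$bias,
             loa_lo = ba$loa[1], loa_hi = ba$loa[2],
             mppe_pct = pe[["mppe"]], mape_pct = pe[["mape"]])
}

hct_img <- estimate_hct(as_model(models$mgv, "MGV"), cohort$mgv)$hct
hct_hb <- estimate_hct(as_model(models$abs, "ABS"), cohort$abs550)$hct
vol_cond <- estimate_volume(cohort$conductivity, conductivity_curves(),
                            policy = "average")$volume
vol_ref <- reference_volume(cohort$true_hct)

rows <- rbind(
  report("image HCT vs reference", cohort$reference_hct, hct_img),
  report("hemoglobin HCT vs reference", cohort$reference_hct, hct_hb),
  report("conductivity volume vs surface-area reference", vol_ref, vol_cond)
)
write.csv(rows, file.path(out, "agreement.csv"), row.names = FALSE)
cat("agreement table written to", file.path(out, "agreement.csv"), "\n")
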