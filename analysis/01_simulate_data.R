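#!/usr/bin/env Rscript
# Generate the synthetic study inputs: five-donor calibrator sets and QC
# replicates for the three HCT methods, the conductivity-volume calibration
# design (5 HCT levels x 5 volumes x 6 replicates), a set of rendered spot
# images, and a 23-sample patient cohort with HCT 0.35-0.46.

suppressPackageStartupMessages(library(dbsbias))
seed <- 20260923L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cal <- generate_calibrators(seed = seed)
write.csv(cal, file.path(out, "calibrators.csv"), row.names = FALSE)
cat(sprintf("calibrators: %d rows (%d donors x %d levels x %d modalities)\n",
            nrow(cal), 5, 5, 3))

for (m in c("mgv", "sa", "abs")) {
  qc <- generate_qc(modality = m, seed = seed)
  write.csv(qc, file.path(out, paste0("qc_", m, ".csv")), row.names = FALSE)
}
cat("QC replicates: n = 5 at HCT 0.2 / 0.4 / 0.6 per modality\n")

cond <- suppressWarnings(generate_conductivity_table(noise = "qc",
                                                     seed = seed))
write.csv(cond, file.path(out, "conductivity.csv"), row.names = FALSE)
cat(sprintf("conductivity table: %d rows; %d below-intercept (negative) readings kept and flagged\n",
            nrow(cond), sum(cond$conductivity < 0)))

for (h in c(0.2, 0.4, 0.6)) {
  img <- generate_spot_image(h, image_noise_sd = 2, seed = seed)
  write_spot_image(img, file.path(out, sprintf("spot_hct%02d.png", 100 * h)))
}
cat("spot images: HCT 0.2 / 0.4 / 0.6 rendered at 0.1 mm/px\n")

cohort <- generate_patient_cohort(n = 23, seed = seed)
write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)
cat(sprintf("patient cohort: %d samples, HCT %.3f-%.3f\n",
            nrow(cohort), min(cohort$true_hct), max(cohort$true_hct)))
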