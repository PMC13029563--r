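Package: dbsbias
Title: Hematocrit and Volume Bias Correction for Dried Blood Spot Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate hematocrit (HCT) and blood volume in dried
    blood spot (DBS) samples and to correct analyte concentrations for the
    resulting bias. HCT is estimated from spot densitometry (mean gray
    value, surface area) or from hemoglobin absorbance at 550 nm; punch
    blood volume is estimated from extract conductivity. Measured blood
    concentrations are converted to plasma concentrations under a blood
    cell-to-plasma partition model, and residual relative error is
    quantified by Monte Carlo propagation of the measurement uncertainty.
    Includes calibration fitting, inversion and bioanalytical validation
    rules, Deming regression, Bland-Altman agreement, MPPE/MAPE, ANCOVA
    slope-heterogeneity tests, and a synthetic-data generator emulating the
    published calibration structure for fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    igraph,
    jsonlite,
    png,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
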