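# shared fixtures: noise-free specs and published-coefficient models

zero_noise <- noise_spec(100, 0)

mgv_model <- function() calibration_model(c(161.67, -237.12, 177.64),
                                          response_name = "MGV")
sa_model <- function() calibration_model(c(-0.0397, 0.0922),
                                         response_name = "SA")
abs_model <- function() calibration_model(c(1.137, 0.003),
                                          response_name = "ABS")

# ANCOVA-style conductivity design: g groups x v covariate points x r reps,
# common slope/intercept unless overridden, iid gaussian noise
slope_design <- function(n_groups = 5, volumes = c(5, 10, 20, 30, 40),
                         reps = 6, slope = 25, intercept = 15, sd = 1,
                         slopes = rep(slope, n_groups)) {
  d <- expand.grid(group = seq_len(n_groups), x = volumes, rep = seq_len(reps))
  d$y <- slopes[d$group] * d$x + intercept + stats::rnorm(nrow(d), 0, sd)
  d
}
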