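#' Published DBS response models
#'
#' Bundle of the response models linking hematocrit (HCT) and blood volume
#' to the measurable quantities of the four DBS methods:
#'
#' * `mgv`: quadratic mean-gray-value model, `MGV = a*HCT^2 + b*HCT + c`
#'   (0-255 gray levels, decreasing in HCT over 0.2-0.6).
#' * `sa`: linear surface-area model `SA = slope*HCT + intercept`
#'   (model units; see `area_scale` in [generate_spot_image()]).
#' * `abs`: linear hemoglobin-absorbance model `ABS = slope*HCT + intercept`
#'   (absorbance at 550 nm after SLS complexation).
#' * `cond_lines`: per-HCT calibration lines `volume_uL = slope*cond + intercept`
#'   relating the blood volume spotted on the card to the conductivity of the
#'   punch extract (uS/cm), one line per HCT level 0.2-0.6.
#' * `cond_pooled`: the pooled ("average") line over all HCT levels.
#' * `punch_volume`: blood volume (uL) contained in a 6 mm punch from a
#'   20 uL spot, by HCT level (average-curve back-calculated values).
#'
#' Defaults are the published calibration coefficients; all can be overridden
#' for simulation studies.
#'
#' @param mgv numeric(3), quadratic coefficients (highest degree first).
#' @param sa numeric(2), linear coefficients (slope, intercept).
#' @param abs numeric(2), linear coefficients (slope, intercept).
#' @param cond_lines data.frame with columns `hct`, `slope`, `intercept`.
#' @param cond_pooled numeric(2), pooled (slope, intercept).
#' @param punch_volume named numeric, punch blood volume (uL) by HCT level.
#'
#' @return An object of class `dbs_models` (a list with the above fields).
#' @examples
#' m <- dbs_models()
#' model_response(m, "abs", 0.4) # 1.137 * 0.4 + 0.003
#' @export
dbs_models <- function(mgv = c(161.67, -237.12, 177.64),
                       sa = c(-0.0397, 0.0922),
                       abs = c(1.137, 0.003),
                       cond_lines = data.frame(
                         hct = c(0.2, 0.3, 0.4, 0.5, 0.6),
                         slope = c(25.97, 26.06, 25.18, 23.01, 23.22),
                         intercept = c(10.19, 13.15, -0.01, 29.78, 27.60)
                       ),
                       cond_pooled = c(24.69, 16.72),
                       punch_volume = c("0.2" = 8.4, "0.3" = 9.5, "0.4" = 9.6,
                                        "0.5" = 10.5, "0.6" = 11.4)) {
  stopifnot(length(mgv) == 3, length(sa) == 2, length(abs) == 2,
            all(c("hct", "slope", "intercept") %in% names(cond_lines)),
            length(cond_pooled) == 2)
  pv <- punch_volume[order(as.numeric(names(punch_volume)))]
  if (any(pv <= 0) || is.unsorted(pv)) {
    stop("punch volumes must be positive and nondecreasing in HCT")
  }
  # the MGV parabola must be decreasing over the calibration range
  d_lo <- 2 * mgv[1] * 0.2 + mgv[2]
  d_hi <- 2 * mgv[1] * 0.6 + mgv[2]
  if (max(d_lo, d_hi) >= 0) {
    warning("MGV model is not monotone decreasing on [0.2, 0.6]")
  }
  structure(list(mgv = mgv, sa = sa, abs = abs,
                 cond_lines = cond_lines, cond_pooled = cond_pooled,
                 punch_volume = pv),
            class = "dbs_models")
}

#' Evaluate a forward response model
#'
#' @param models a [dbs_models()] object.
#' @param modality one of `"mgv"`, `"sa"`, `"abs"`.
#' @param hct hematocrit fraction(s).
#' @return Numeric vector of noise-free responses.
#' @export
model_response <- function(models, modality, hct) {
  modality <- match.arg(modality, c("mgv", "sa", "abs"))
  cf <- models[[modality]]
  if (modality == "mgv") {
    cf[1] * hct^2 + cf[2] * hct + cf[3]
  } else {
    cf[1] * hct + cf[2]
  }
}

#' Blood volume in a 6 mm punch as a function of HCT
#'
#' Piecewise-linear interpolation of the punch blood volumes by HCT level
#' stored in `models$punch_volume`; constant extrapolation outside the
#' tabulated range.
#'
#' @inheritParams model_response
#' @param hct hematocrit fraction(s).
#' @return Punch blood volume(s) in uL.
#' @examples
#' punch_volume(dbs_models(), 0.4) # 9.6
#' @export
punch_volume <- function(models, hct) {
  pv <- models$punch_volume
  stats::approx(as.numeric(names(pv)), pv, xout = hct, rule = 2)$y
}

#' Measurement-noise specification
#'
#' Accuracy (mean recovery, percent of nominal) and precision (relative
#' standard deviation, percent) of a measurement, as reported for QC samples.
#' Noise is multiplicative Gaussian: a measured value is
#' `truth * accuracy/100 * (1 + e)`, `e ~ N(0, rsd/100)` truncated at +/- 4 SD
#' so that responses stay positive.
#'
#' @param accuracy_pct mean recovery in percent (> 0); 100 = unbiased.
#' @param rsd_pct relative standard deviation in percent (>= 0).
#' @param distribution noise family; only `"gaussian"` is supported.
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(99.1, 5.87)
#' @export
noise_spec <- function(accuracy_pct = 100, rsd_pct = 0,
                       distribution = "gaussian") {
  distribution <- match.arg(distribution, "gaussian")
  stopifnot(accuracy_pct > 0, rsd_pct >= 0)
  structure(list(accuracy_pct = accuracy_pct, rsd_pct = rsd_pct,
                 distribution = distribution),
            class = "noise_spec")
}

#' Published QC accuracy and precision by method
#'
#' The QC accuracy/precision values reported for each method at the low
#' (HCT 0.2), medium (0.4) and high (0.6) QC levels. These are the default
#' noise magnitudes for synthetic data generation and for the Monte Carlo
#' error propagation.
#'
#' @param method one of `"mgv"`, `"sa"`, `"abs"` (hemoglobin), `"cond"`.
#' @return data.frame with columns `level`, `accuracy_pct`, `rsd_pct`.
#' @examples
#' qc_noise_table("abs")
#' @export
qc_noise_table <- function(method = c("mgv", "sa", "abs", "cond")) {
  method <- match.arg(method)
  tab <- switch(method,
    mgv  = data.frame(level = c(0.2, 0.4, 0.6),
                      accuracy_pct = c(90.3, 93.2, 98.8),
                      rsd_pct = c(0.87, 2.71, 4.77)),
    sa   = data.frame(level = c(0.2, 0.4, 0.6),
                      accuracy_pct = c(103, 103, 99.6),
                      rsd_pct = c(11.3, 5.73, 5.63)),
    abs  = data.frame(level = c(0.2, 0.4, 0.6),
                      accuracy_pct = c(102.2, 95.7, 99.1),
                      rsd_pct = c(2.45, 7.44, 5.87)),
    cond = data.frame(level = c(0.2, 0.4, 0.6),
                      accuracy_pct = c(96.8, 100, 99.6),
                      rsd_pct = c(13.6, 5.57, 5.14))
  )
  tab
}

#' Noise spec at the QC level nearest a given level
#'
#' @inheritParams qc_noise_table
#' @param level the HCT level (or scenario truth) to match.
#' @return A [noise_spec()].
#' @export
qc_noise_at <- function(method, level) {
  tab <- qc_noise_table(method)
  i <- which.min(abs(tab$level - level))
  noise_spec(tab$accuracy_pct[i], tab$rsd_pct[i])
}

#' Per-level RSD by linear interpolation of the printed QC precisions
#'
#' The QC table reports precision only at levels 0.2, 0.4 and 0.6; for
#' intermediate calibrator levels the RSD is interpolated linearly
#' (constant beyond the end levels).
#'
#' @inheritParams qc_noise_at
#' @return RSD in percent at `level` (vectorised).
#' @export
qc_rsd_interp <- function(method, level) {
  tab <- qc_noise_table(method)
  stats::approx(tab$level, tab$rsd_pct, xout = level, rule = 2)$y
}

#' Printed precision converted to response-space RSD
#'
#' The QC precisions are relative standard deviations of *back-calculated*
#' levels. A generator drawing noise on the raw response needs the
#' equivalent response-space RSD, obtained by the delta method:
#' `rsd_response = rsd_level * level * |f'(level)| / f(level)` for forward
#' model `f`. For the absorbance line (near-zero intercept) the two are
#' almost identical; for the flat MGV parabola the response-space RSD is
#' several-fold smaller.
#'
#' @param models a [dbs_models()] bundle.
#' @param modality one of `"mgv"`, `"sa"`, `"abs"`.
#' @param level HCT level(s).
#' @return Response-space RSD in percent (vectorised).
#' @export
response_rsd_interp <- function(models, modality, level) {
  rsd_level <- qc_rsd_interp(modality, level)
  f <- model_response(models, modality, level)
  cf <- models[[modality]]
  deriv <- if (modality == "mgv") 2 * cf[1] * level + cf[2] else cf[1]
  rsd_level * level * abs(deriv) / abs(f)
}

# Deterministic sub-seed for a labelled random stream: changing one
# modality's parameters must not perturb the draws of the others.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 1009)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Multiplicative truncated-gaussian measurement noise around `truth`.
# Truncation at +/- 4 SD keeps responses positive for all printed RSDs.
apply_noise <- function(truth, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- length(truth)
  eps <- stats::rnorm(n, 0, 1)
  bad <- abs(eps) > 4
  while (any(bad)) {
    eps[bad] <- stats::rnorm(sum(bad), 0, 1)
    bad <- abs(eps) > 4
  }
  truth * noise$accuracy_pct / 100 * (1 + eps * noise$rsd_pct / 100)
}
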