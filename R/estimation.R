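#' @title HCT and punch-volume estimation
#' @description Applies the fitted calibrations to estimate hematocrit
#'   (from MGV, surface area or absorbance) and the blood volume in a punch
#'   (from extract conductivity, with either an HCT-specific or the pooled
#'   "average" curve), plus the published surface-area reference volume
#'   model.
#' @name estimation
NULL

#' Estimate HCT from a calibrated measurement
#'
#' Inverse prediction through the calibration model, clamped to the
#' physical support [0, 1] with a flag instead of an error: patient
#' samples may legitimately fall slightly outside the calibrator range.
#'
#' @param model a `calibration_model` whose predictor is HCT.
#' @param value measured response(s) (MGV, SA or ABS).
#' @return data.frame with columns `hct`, `out_of_range` (outside the
#'   model's fitted range), `clamped` (truncated to \[0, 1\]).
#' @examples
#' m <- calibration_model(c(1.137, 0.003), response_name = "ABS")
#' estimate_hct(m, 0.4578)$hct # 0.400
#' @export
estimate_hct <- function(model, value) {
  x <- invert_calibration(model, value, clip = TRUE)
  oor <- attr(x, "out_of_range")
  clamped <- x < 0 | x > 1
  data.frame(hct = pmin(pmax(as.numeric(x), 0), 1),
             out_of_range = oor, clamped = clamped)
}

#' Fit per-HCT and pooled conductivity-volume calibration curves
#'
#' Fits `volume ~ conductivity` separately within each HCT level and
#' pooled over all points (the "average" curve). The arithmetic mean of
#' the per-level coefficients is also reported: with a balanced design the
#' pooled OLS slope equals the mean of the per-level slopes.
#'
#' @param tbl data.frame with columns `hct`, `volume`, `conductivity`
#'   (e.g. from [generate_conductivity_table()]).
#' @return List with `per_hct` (named list of `calibration_model` keyed by
#'   HCT level), `pooled` (a `calibration_model`), and `mean_of_levels`
#'   (slope, intercept).
#' @export
fit_conductivity_curves <- function(tbl) {
  stopifnot(all(c("hct", "volume", "conductivity") %in% names(tbl)))
  per <- lapply(split(tbl, tbl$hct), function(d) {
    fit_calibration(d$conductivity, d$volume, "linear",
                    predictor_name = "conductivity",
                    response_name = "volume")
  })
  pooled <- fit_calibration(tbl$conductivity, tbl$volume, "linear",
                            predictor_name = "conductivity",
                            response_name = "volume")
  cf <- vapply(per, function(m) m$coefficients, numeric(2))
  list(per_hct = per, pooled = pooled,
       mean_of_levels = c(slope = mean(cf[1, ]), intercept = mean(cf[2, ])))
}

#' Published conductivity-volume curves as calibration models
#'
#' Wraps the per-HCT and pooled conductivity-volume coefficients stored in
#' a [dbs_models()] bundle into `calibration_model` objects, in the list
#' structure [estimate_volume()] expects. Useful when estimation should use
#' the published (validated) curves rather than curves refitted from data.
#'
#' @param models a [dbs_models()] bundle.
#' @param cond_range conductivity validity range recorded on the curves.
#' @return List with `per_hct` (named by HCT level) and `pooled`.
#' @export
conductivity_curves <- function(models = dbs_models(),
                                cond_range = c(-1.1, 1.7)) {
  per <- lapply(seq_len(nrow(models$cond_lines)), function(i) {
    calibration_model(c(models$cond_lines$slope[i],
                        models$cond_lines$intercept[i]),
                      range = cond_range,
                      predictor_name = "conductivity",
                      response_name = "volume")
  })
  names(per) <- models$cond_lines$hct
  list(per_hct = per,
       pooled = calibration_model(models$cond_pooled, range = cond_range,
                                  predictor_name = "conductivity",
                                  response_name = "volume"))
}

#' Estimate blood volume in a punch from conductivity
#'
#' `volume = slope * conductivity + intercept` with either the pooled
#' ("average") curve or the curve of the nearest HCT level. The `auto`
#' policy encodes the decision rule used for the patient cohort: use the
#' average curve when the estimated HCT lies inside `band` (default
#' 0.35-0.46, the cohort range that justified it), else the nearest
#' HCT-specific curve.
#'
#' @param cond conductivity value(s) in uS/cm.
#' @param curves output of [fit_conductivity_curves()], or a list with the
#'   same structure built from published coefficients.
#' @param hct_estimate estimated HCT fraction (required for
#'   `"hct_specific"`, used by `"auto"`).
#' @param policy `"average"`, `"hct_specific"` or `"auto"`.
#' @param band HCT band within which `auto` uses the average curve.
#' @return data.frame with columns `volume` (uL), `curve_used`, and flag
#'   columns `negative_conductivity` and `out_of_range` (conductivity
#'   outside the curve's fitted range, when known).
#' @examples
#' curves <- list(pooled = calibration_model(c(24.7, 16.7), range = c(0, 1),
#'                predictor_name = "conductivity", response_name = "volume"))
#' estimate_volume(0.943, curves, policy = "average")$volume # 40.0
#' @export
estimate_volume <- function(cond, curves, hct_estimate = NULL,
                            policy = c("auto", "average", "hct_specific"),
                            band = c(0.35, 0.46)) {
  policy <- match.arg(policy)
  if (policy == "hct_specific" && is.null(hct_estimate)) {
    stop("policy 'hct_specific' requires an HCT estimate")
  }
  pick <- function() {
    if (policy == "average") return(list(m = curves$pooled, used = "average"))
    if (policy == "auto") {
      if (is.null(hct_estimate) ||
          (hct_estimate >= band[1] && hct_estimate <= band[2])) {
        return(list(m = curves$pooled, used = "average"))
      }
    }
    levels <- as.numeric(names(curves$per_hct))
    i <- which.min(abs(levels - hct_estimate))
    list(m = curves$per_hct[[i]],
         used = paste0("hct_specific(", levels[i], ")"))
  }
  sel <- pick()
  cf <- sel$m$coefficients
  vol <- cf[1] * cond + cf[2]
  oor <- if (all(is.finite(sel$m$range))) {
    cond < sel$m$range[1] | cond > sel$m$range[2]
  } else {
    rep(FALSE, length(cond))
  }
  # a reading at or below zero is physically implausible (meters bottom out
  # near 0.01 uS/cm) but arises from the printed line algebra; flag, keep
  data.frame(volume = vol, curve_used = sel$used,
             negative_conductivity = cond <= 0, out_of_range = oor)
}

#' Reference punch blood volume from the surface-area model
#'
#' The published surface-area reference model relates spot surface area
#' (SA, scanner units) to blood volume (BV, uL) and hematocrit in percent:
#' `SA = 690.414 * BV - 72.3 * HCT% + 3941.8`. For a 6 mm punch the
#' surface area is the constant 7780, so the punch blood volume follows by
#' solving for BV. The model is increasing in HCT: a punch from a
#' higher-HCT spot holds more blood.
#'
#' @param hct hematocrit fraction(s) in (0, 1).
#' @param punch_sa punch surface area in model units (6 mm punch: 7780).
#' @param coef_bv,coef_hct,intercept model coefficients.
#' @return Punch blood volume(s) in uL.
#' @examples
#' reference_volume(0.40) # 9.749
#' @export
reference_volume <- function(hct, punch_sa = 7780, coef_bv = 690.414,
                             coef_hct = 72.3, intercept = 3941.8) {
  if (any(hct <= 0 | hct >= 1)) stop("hct must lie strictly inside (0, 1)")
  (punch_sa + coef_hct * (100 * hct) - intercept) / coef_bv
}
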