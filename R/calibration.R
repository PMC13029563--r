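#' @title Calibration fitting, inversion and validation
#' @description Ordinary least-squares calibration models (linear or
#'   quadratic), their inverse prediction, and the bioanalytical acceptance
#'   rules applied to calibrator back-calculation and QC accuracy/precision.
#' @name calibration
NULL

#' Fit a calibration model
#'
#' Ordinary least squares in the response-on-predictor direction, linear
#' (`y = m x + b`) or quadratic (`y = a x^2 + b x + c`). Coefficients are
#' stored highest degree first; the validity range is the span of the
#' fitted predictors. A constant response is a degenerate but valid fit
#' with slope 0 and, by convention, `r2 = 0`.
#'
#' @param predictor numeric predictor values (HCT fraction, conductivity...).
#' @param response numeric responses (MGV, SA, ABS, volume...).
#' @param kind `"linear"` or `"quadratic"`.
#' @param predictor_name,response_name labels carried in the model.
#' @return Object of class `calibration_model`: list with `kind`,
#'   `coefficients` (highest degree first), `predictor`, `response`,
#'   `range`, `r2`.
#' @examples
#' h <- seq(0.2, 0.6, 0.1)
#' fit_calibration(h, 1.137 * h + 0.003)            # recovers (1.137, 0.003)
#' @export
fit_calibration <- function(predictor, response,
                            kind = c("linear", "quadratic"),
                            predictor_name = "predictor",
                            response_name = "response") {
  kind <- match.arg(kind)
  stopifnot(length(predictor) == length(response))
  p <- if (kind == "linear") 2L else 3L
  if (length(predictor) < p + 1L) {
    stop("need at least ", p + 1L, " points for a ", kind, " fit")
  }
  if (length(unique(predictor)) < p) {
    stop("rank-deficient design: fewer than ", p, " distinct predictor values")
  }
  fit <- if (kind == "linear") {
    stats::lm(response ~ predictor)
  } else {
    stats::lm(response ~ I(predictor^2) + predictor)
  }
  cf <- stats::coef(fit)
  coefficients <- if (kind == "linear") {
    c(unname(cf["predictor"]), unname(cf["(Intercept)"]))
  } else {
    c(unname(cf["I(predictor^2)"]), unname(cf["predictor"]),
      unname(cf["(Intercept)"]))
  }
  sstot <- sum((response - mean(response))^2)
  r2 <- if (sstot == 0) 0 else 1 - sum(stats::resid(fit)^2) / sstot
  structure(list(kind = kind, coefficients = coefficients,
                 predictor = predictor_name, response = response_name,
                 range = range(predictor), r2 = r2),
            class = "calibration_model")
}

#' Construct a calibration model from known coefficients
#'
#' Wraps published coefficients (rather than a fresh fit) in the same
#' container used by [fit_calibration()].
#'
#' @param coefficients highest degree first (length 2 linear, 3 quadratic).
#' @param range predictor validity range `(lo, hi)`.
#' @param r2 coefficient of determination, if known.
#' @inheritParams fit_calibration
#' @return A `calibration_model`.
#' @examples
#' calibration_model(c(1.137, 0.003), range = c(0.2, 0.6), r2 = 0.9939)
#' @export
calibration_model <- function(coefficients, range = c(0.2, 0.6), r2 = NA_real_,
                              predictor_name = "HCT",
                              response_name = "response") {
  kind <- switch(as.character(length(coefficients)),
                 "2" = "linear", "3" = "quadratic",
                 stop("coefficients must have length 2 or 3"))
  stopifnot(range[1] < range[2])
  structure(list(kind = kind, coefficients = as.numeric(coefficients),
                 predictor = predictor_name, response = response_name,
                 range = as.numeric(range), r2 = r2),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  eq <- if (x$kind == "linear") {
    sprintf("%s = %.6g * %s + %.6g", x$response, x$coefficients[1],
            x$predictor, x$coefficients[2])
  } else {
    sprintf("%s = %.6g * %s^2 + %.6g * %s + %.6g", x$response,
            x$coefficients[1], x$predictor, x$coefficients[2], x$predictor,
            x$coefficients[3])
  }
  cat(sprintf("<calibration_model> %s  [%g, %g], r2 = %.4g\n",
              eq, x$range[1], x$range[2], x$r2))
  invisible(x)
}

#' Predict the response of a calibration model
#'
#' @param object a `calibration_model`.
#' @param newdata predictor values.
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  cf <- object$coefficients
  if (object$kind == "linear") cf[1] * newdata + cf[2]
  else cf[1] * newdata^2 + cf[2] * newdata + cf[3]
}

#' Invert a calibration model (inverse prediction)
#'
#' Back-calculates the predictor from a measured response. Linear models
#' invert exactly; quadratic models return the smaller real root — the
#' branch left of the parabola's vertex, on which the MGV model is
#' monotone decreasing over its calibration range. Results outside the
#' model's fitted range are returned with an `out_of_range` flag rather
#' than an error.
#'
#' @param model a `calibration_model`.
#' @param response measured response value(s).
#' @param clip for quadratic models, censor responses beyond the
#'   parabola's vertex at the vertex (returning the vertex predictor,
#'   flagged out of range) instead of erroring on complex roots. Used by
#'   the estimation and validation layers, where a noisy response just
#'   past the turning point is a legitimate observation.
#' @return Numeric vector of back-calculated predictor values with a
#'   logical attribute `out_of_range`.
#' @examples
#' m <- calibration_model(c(161.67, -237.12, 177.64))
#' invert_calibration(m, 136.68) # 0.200
#' @export
invert_calibration <- function(model, response, clip = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  cf <- model$coefficients
  x <- if (model$kind == "linear") {
    if (cf[1] == 0) stop("cannot invert a zero-slope calibration")
    (response - cf[2]) / cf[1]
  } else {
    disc <- cf[2]^2 - 4 * cf[1] * (cf[3] - response)
    if (any(disc < 0)) {
      if (!clip) stop("response outside the parabola's reach (complex roots)")
      disc <- pmax(disc, 0)
    }
    # smaller root = monotone-decreasing branch left of the vertex
    (-cf[2] - sqrt(disc)) / (2 * cf[1])
  }
  attr(x, "out_of_range") <- x < model$range[1] | x > model$range[2]
  x
}

#' Validate a calibration against bioanalytical acceptance rules
#'
#' Applies the standard acceptance rules: the per-level mean back-calculated
#' calibrator value must be within +/-15% of nominal (+/-20% at the lowest
#' level, the LLOQ), QC accuracy must fall within 85-115% of nominal, and
#' QC precision (RSD, n-1 sample SD over mean) must stay below 15%.
#'
#' @param model a `calibration_model` fitted to the calibrators.
#' @param calibrators data.frame with columns `level` and `response`.
#' @param qc data.frame with columns `level` and `response` (>= 2 replicates
#'   per level).
#' @param cal_tol_pct calibrator tolerance (percent deviation).
#' @param lloq_tol_pct tolerance at the LLOQ (lowest calibrator level).
#' @param acc_range acceptable QC accuracy window in percent.
#' @param rsd_max_pct maximum acceptable QC RSD in percent.
#' @param per_replicate if `TRUE`, calibrator deviations are assessed per
#'   replicate instead of on per-level means.
#' @return Object of class `validation_report`: list with data.frames
#'   `calibrator` (level, mean_back, deviation_pct, tolerance_pct, pass),
#'   `qc` (level, n, accuracy_pct, rsd_pct, pass), the `lloq_level`, and
#'   the overall `pass` flag.
#' @export
validate_calibration <- function(model, calibrators, qc,
                                 cal_tol_pct = 15, lloq_tol_pct = 20,
                                 acc_range = c(85, 115), rsd_max_pct = 15,
                                 per_replicate = FALSE) {
  stopifnot(all(c("level", "response") %in% names(calibrators)),
            all(c("level", "response") %in% names(qc)))
  if (any(calibrators$level == 0) || any(qc$level == 0)) {
    stop("nominal level of zero: percent deviation undefined")
  }
  lloq <- min(calibrators$level)

  back <- invert_calibration(model, calibrators$response, clip = TRUE)
  cal_split <- split(data.frame(level = calibrators$level, back = back),
                     calibrators$level)
  cal <- do.call(rbind, lapply(cal_split, function(d) {
    nominal <- d$level[1]
    if (per_replicate) {
      dev <- 100 * (d$back - nominal) / nominal
      dev_rep <- dev[which.max(abs(dev))]
    } else {
      dev_rep <- 100 * (mean(d$back) - nominal) / nominal
    }
    tol <- if (nominal == lloq) lloq_tol_pct else cal_tol_pct
    data.frame(level = nominal, mean_back = mean(d$back),
               deviation_pct = dev_rep, tolerance_pct = tol,
               pass = abs(dev_rep) <= tol)
  }))
  rownames(cal) <- NULL

  qc_split <- split(qc, qc$level)
  if (any(vapply(qc_split, nrow, 0L) < 2)) {
    stop("each QC level needs at least 2 replicates")
  }
  qc_rep <- do.call(rbind, lapply(qc_split, function(d) {
    nominal <- d$level[1]
    b <- invert_calibration(model, d$response, clip = TRUE)
    acc <- 100 * mean(b) / nominal
    rsd <- 100 * stats::sd(b) / mean(b)
    data.frame(level = nominal, n = nrow(d), accuracy_pct = acc,
               rsd_pct = rsd,
               pass = acc >= acc_range[1] & acc <= acc_range[2] &
                 rsd < rsd_max_pct)
  }))
  rownames(qc_rep) <- NULL

  structure(list(calibrator = cal, qc = qc_rep, lloq_level = lloq,
                 pass = all(cal$pass) && all(qc_rep$pass)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("Calibrators (LLOQ level ", x$lloq_level, "):\n", sep = "")
  print(x$calibrator, row.names = FALSE, digits = 4)
  cat("QC:\n")
  print(x$qc, row.names = FALSE, digits = 4)
  invisible(x)
}
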