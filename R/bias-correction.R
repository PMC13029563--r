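#' @title Plasma-concentration correction and error propagation
#' @description Converts a measured DBS blood concentration to a plasma
#'   concentration under the blood cell-to-plasma partition model and
#'   quantifies the residual relative error of each correction strategy by
#'   Monte Carlo propagation of the HCT and volume measurement uncertainty.
#' @name bias-correction
NULL

#' Convert blood concentration to plasma concentration
#'
#' `Cp = Cb * Vnom / (Vpred * (1 - HCT + K*HCT))`: the partition factor
#' `1 - HCT + K*HCT` maps the whole-blood concentration to plasma given
#' the blood cell-to-plasma partition coefficient K (0 = excluded from
#' cells, 1 = even distribution, >1 = accumulation in cells), and the
#' volume ratio re-references the analyte amount from the nominal to the
#' predicted punch volume. At K = 1 the partition factor is 1 for any HCT.
#'
#' @param cb measured blood concentration (any concentration unit).
#' @param hct hematocrit fraction used for the correction, in \[0, 1).
#' @param k blood cell-to-plasma partition coefficient (>= 0).
#' @param vpred predicted (measured) punch blood volume, uL.
#' @param vnom nominal (assumed) punch blood volume, uL.
#' @return Plasma concentration(s), same unit as `cb`.
#' @examples
#' plasma_concentration(100, hct = 0.5, k = 0) # 200
#' @export
plasma_concentration <- function(cb, hct, k, vpred = 1, vnom = 1) {
  stopifnot(all(hct >= 0), all(hct < 1), all(k >= 0),
            all(vpred > 0), all(vnom > 0))
  f <- 1 - hct + k * hct
  if (any(f <= 0)) stop("non-positive partition factor")
  cb * vnom / (vpred * f)
}

#' Monte Carlo scenario for the correction-error simulation
#'
#' Defines one cell of the error grid: the sample's true HCT and the
#' analyte's partition coefficient K, the correction strategy, and the
#' measurement noise of the corrections. Defaults follow the published
#' simulation design: HCT measured by the hemoglobin method (its QC
#' accuracy/precision at the level nearest the true HCT), punch volume by
#' the conductivity method (same rule), assumed HCT 0.4 and nominal punch
#' volume 9.6 uL (the punch volume at HCT 0.4) in the uncorrected arms,
#' and 100,000 draws.
#'
#' @param true_hct the sample's true hematocrit fraction.
#' @param k blood cell-to-plasma partition coefficient.
#' @param strategy `"none"`, `"hct_only"`, `"volume_only"` or `"both"` —
#'   which measured corrections enter the estimate.
#' @param hct_noise [noise_spec()] of the HCT measurement; default the
#'   hemoglobin-method QC values nearest `true_hct`.
#' @param volume_noise [noise_spec()] of the volume measurement; default
#'   the conductivity-method QC values nearest `true_hct`.
#' @param assumed_hct HCT assumed when not corrected.
#' @param vnom nominal punch volume (uL) assumed when not corrected.
#' @param n_draws Monte Carlo draws.
#' @param seed scenario seed.
#' @param sample_vpred_uncorrected if `TRUE`, uncorrected-volume arms also
#'   sample `Vpred` around the truth instead of fixing `Vpred = Vnom`
#'   (pure assumption error, the default).
#' @return Object of class `mc_scenario`.
#' @export
mc_scenario <- function(true_hct, k,
                        strategy = c("none", "hct_only", "volume_only", "both"),
                        hct_noise = NULL, volume_noise = NULL,
                        assumed_hct = 0.4, vnom = 9.6,
                        n_draws = 1e5, seed = 1L,
                        sample_vpred_uncorrected = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(true_hct > 0, true_hct < 1, k >= 0, n_draws >= 1)
  structure(list(
    true_hct = true_hct, k = k, strategy = strategy,
    hct_noise = hct_noise %||% qc_noise_at("abs", true_hct),
    volume_noise = volume_noise %||% qc_noise_at("cond", true_hct),
    assumed_hct = assumed_hct, vnom = vnom,
    n_draws = as.integer(n_draws), seed = seed,
    sample_vpred_uncorrected = sample_vpred_uncorrected
  ), class = "mc_scenario")
}

#' Simulate the relative error of a correction strategy
#'
#' One scenario of the error grid. Per draw, the true state is a plasma
#' concentration of 1 at the scenario's true HCT and the true punch volume
#' from the punch-volume model; the observed blood concentration is the
#' partition-model blood concentration referenced to the nominal punch
#' volume (`Cb_obs = Cb_true * V_true / Vnom`). The estimate then applies
#' [plasma_concentration()] with measured HCT and/or measured volume
#' (normal, mean `truth * accuracy/100`, SD `mean * RSD/100`) when the
#' strategy corrects them, and the assumed HCT / nominal volume otherwise.
#' Draws with HCT outside (0, 1) or non-positive volume are redrawn. The
#' summary is the median and the 2.5th/97.5th percentiles (linear
#' interpolation between order statistics) of the relative error in
#' percent.
#'
#' @param scenario an [mc_scenario()].
#' @param models a [dbs_models()] bundle (punch-volume truth).
#' @return Object of class `error_summary`: list with `median_rel_err`,
#'   `p2_5`, `p97_5` (percent) and the scenario descriptors.
#' @examples
#' s <- mc_scenario(0.6, k = 0, strategy = "both",
#'                  hct_noise = noise_spec(100, 0),
#'                  volume_noise = noise_spec(100, 0), n_draws = 10)
#' simulate_relative_error(s)$median_rel_err # exactly 0
#' @export
simulate_relative_error <- function(scenario, models = dbs_models()) {
  stopifnot(inherits(scenario, "mc_scenario"))
  sc <- scenario
  v_true <- punch_volume(models, sc$true_hct)
  cb_true <- 1 * (1 - sc$true_hct + sc$k * sc$true_hct)
  cb_obs <- cb_true * v_true / sc$vnom

  rel <- with_local_seed(sc$seed, {
    n <- sc$n_draws
    h <- if (sc$strategy %in% c("hct_only", "both")) {
      truncated_normal(n, sc$true_hct * sc$hct_noise$accuracy_pct / 100,
                       sc$true_hct * sc$hct_noise$accuracy_pct / 100 *
                         sc$hct_noise$rsd_pct / 100,
                       lower = 0, upper = 1, strict = TRUE)
    } else {
      rep(sc$assumed_hct, n)
    }
    v <- if (sc$strategy %in% c("volume_only", "both")) {
      truncated_normal(n, v_true * sc$volume_noise$accuracy_pct / 100,
                       v_true * sc$volume_noise$accuracy_pct / 100 *
                         sc$volume_noise$rsd_pct / 100,
                       lower = 0, strict = TRUE)
    } else if (sc$sample_vpred_uncorrected) {
      truncated_normal(n, v_true * sc$volume_noise$accuracy_pct / 100,
                       v_true * sc$volume_noise$accuracy_pct / 100 *
                         sc$volume_noise$rsd_pct / 100,
                       lower = 0, strict = TRUE)
    } else {
      rep(sc$vnom, n)
    }
    cp_est <- plasma_concentration(cb_obs, h, sc$k, vpred = v, vnom = sc$vnom)
    100 * (cp_est - 1) / 1
  })

  q <- stats::quantile(rel, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  structure(list(true_hct = sc$true_hct, k = sc$k, strategy = sc$strategy,
                 median_rel_err = q[1], p2_5 = q[2], p97_5 = q[3],
                 n_draws = sc$n_draws),
            class = "error_summary")
}

# Normal draws with redraw outside (lower, upper); strict = open interval.
truncated_normal <- function(n, mean, sd, lower = -Inf, upper = Inf,
                             strict = FALSE) {
  x <- stats::rnorm(n, mean, sd)
  out_of_support <- function(x) {
    if (strict) x <= lower | x >= upper else x < lower | x > upper
  }
  bad <- out_of_support(x)
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out_of_support(x)
  }
  x
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "<error_summary> HCT %.2g, K %g, %s: median %.2f%% [%.2f, %.2f]\n",
    x$true_hct, x$k, x$strategy, x$median_rel_err, x$p2_5, x$p97_5))
  invisible(x)
}

#' Run the full correction-error grid
#'
#' Full factorial over true HCT, partition coefficient K and correction
#' strategy; each cell runs [simulate_relative_error()] on an independent
#' seed substream so cells are reproducible in isolation.
#'
#' @param hcts true HCT values.
#' @param ks partition coefficients.
#' @param strategies correction strategies.
#' @param n_draws draws per cell.
#' @param seed master seed.
#' @param models a [dbs_models()] bundle.
#' @param ... passed to [mc_scenario()] (noise overrides etc.).
#' @return data.frame with one row per cell: `true_hct`, `k`, `strategy`,
#'   `median_rel_err`, `p2_5`, `p97_5` (percent).
#' @export
run_error_grid <- function(hcts = c(0.2, 0.4, 0.6), ks = c(0, 1, 10),
                           strategies = c("none", "hct_only",
                                          "volume_only", "both"),
                           n_draws = 1e5, seed = 1L,
                           models = dbs_models(), ...) {
  stopifnot(length(hcts) > 0, length(ks) > 0, length(strategies) > 0)
  grid <- expand.grid(true_hct = hcts, k = ks, strategy = strategies,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    sc <- mc_scenario(cell$true_hct, cell$k, cell$strategy,
                      n_draws = n_draws,
                      seed = substream_seed(seed,
                        paste("grid", cell$true_hct, cell$k, cell$strategy)),
                      ...)
    s <- simulate_relative_error(sc, models)
    data.frame(true_hct = s$true_hct, k = s$k, strategy = s$strategy,
               median_rel_err = s$median_rel_err, p2_5 = s$p2_5,
               p97_5 = s$p97_5)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
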