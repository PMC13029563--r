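#' @title Synthetic DBS data generation
#' @description Generators for every input the bias-correction workflow
#'   consumes: calibrator/QC tables, rasterised spot images, conductivity
#'   tables and patient cohorts, all driven by the published response models
#'   plus printed QC noise, and fully reproducible under a fixed seed.
#' @name synthetic-data
NULL

# Evaluate expr under a local RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate synthetic DBS calibrator responses
#'
#' Simulates the five-donor calibration design: each donor contributes one
#' response per HCT level and modality, drawn from the forward model with
#' multiplicative Gaussian noise (see [noise_spec()]). Each modality uses an
#' independent substream of the master seed, so altering one modality's
#' noise leaves the others' draws unchanged.
#'
#' @param n_donors number of donors (>= 1).
#' @param hct_levels ascending HCT fractions in (0, 1).
#' @param modalities subset of `"mgv"`, `"sa"`, `"abs"`.
#' @param models a [dbs_models()] bundle.
#' @param noise named list of [noise_spec()] per modality, a single
#'   [noise_spec()] recycled to all, or `"qc"` to use the per-level RSD
#'   interpolated from the printed QC precisions and converted to response
#'   space (see [response_rsd_interp()]; accuracy 100).
#' @param seed master seed (integer).
#' @return data.frame with columns `donor`, `level`, `modality`, `response`.
#' @examples
#' cal <- generate_calibrators(noise = noise_spec(100, 0), seed = 1)
#' subset(cal, modality == "abs" & level == 0.4)$response # 0.4578 for all
#' @export
generate_calibrators <- function(n_donors = 5,
                                 hct_levels = seq(0.2, 0.6, by = 0.1),
                                 modalities = c("mgv", "sa", "abs"),
                                 models = dbs_models(),
                                 noise = "qc",
                                 seed = 1L) {
  if (length(hct_levels) == 0) stop("empty HCT level list")
  stopifnot(n_donors >= 1, all(hct_levels > 0), all(hct_levels < 1),
            !is.unsorted(hct_levels))
  bad <- setdiff(modalities, c("mgv", "sa", "abs"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))

  out <- lapply(modalities, function(mod) {
    grid <- expand.grid(donor = seq_len(n_donors), level = hct_levels,
                        KEEP.OUT.ATTRS = FALSE)
    truth <- model_response(models, mod, grid$level)
    ns <- resolve_noise(noise, mod, grid$level, models)
    resp <- with_local_seed(substream_seed(seed, mod), {
      vapply(seq_len(nrow(grid)),
             function(i) apply_noise(truth[i], ns[[i]]), numeric(1))
    })
    data.frame(grid, modality = mod, response = resp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("donor", "level", "modality", "response")]
}

# Resolve a noise argument to a list of per-observation noise_spec objects.
# "qc" = unbiased, with the printed (back-calculated) per-level precision
# interpolated and converted to response space.
resolve_noise <- function(noise, modality, levels, models = dbs_models()) {
  if (identical(noise, "qc")) {
    rsd <- response_rsd_interp(models, modality, levels)
    return(lapply(rsd, function(r) noise_spec(100, r)))
  }
  if (inherits(noise, "noise_spec")) return(rep(list(noise), length(levels)))
  if (is.list(noise)) {
    ns <- noise[[modality]]
    if (is.null(ns)) stop("no noise spec for modality '", modality, "'")
    return(resolve_noise(ns, modality, levels, models))
  }
  stop("invalid noise specification")
}

#' Generate synthetic QC replicates
#'
#' QC samples at the low/medium/high levels. The printed QC accuracy and
#' precision describe the *back-calculated* levels, so noise is drawn in
#' level space — `measured_level = level * accuracy/100 * (1 + e)`,
#' `e ~ N(0, rsd/100)` truncated at +/-4 SD — and mapped through the
#' forward response model. Back-calculating the generated responses
#' therefore reproduces the printed accuracy and precision for any model
#' shape, including the flat MGV parabola.
#'
#' @param levels QC levels (HCT fractions).
#' @param n_replicates replicates per level.
#' @param modality the measured modality (`"mgv"`, `"sa"`, `"abs"`).
#' @param models a [dbs_models()] bundle.
#' @param noise `"qc"` (printed accuracy/precision at the nearest QC level)
#'   or a [noise_spec()] applied, in level space, to all levels.
#' @param seed master seed.
#' @return data.frame with columns `level`, `replicate`, `response`.
#' @export
generate_qc <- function(levels = c(0.2, 0.4, 0.6), n_replicates = 5,
                        modality = "abs", models = dbs_models(),
                        noise = "qc", seed = 1L) {
  stopifnot(n_replicates >= 1)
  grid <- expand.grid(level = levels, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$level, grid$replicate), ]
  specs <- if (inherits(noise, "noise_spec")) {
    rep(list(noise), nrow(grid))
  } else {
    lapply(grid$level, function(l) qc_noise_at(modality, l))
  }
  measured <- with_local_seed(substream_seed(seed, paste0("qc-", modality)), {
    vapply(seq_len(nrow(grid)),
           function(i) apply_noise(grid$level[i], specs[[i]]), numeric(1))
  })
  data.frame(level = grid$level, replicate = grid$replicate,
             response = model_response(models, modality, measured),
             row.names = NULL)
}

#' Render a synthetic DBS spot image
#'
#' Draws a filled disc on a white (gray 255) background. The interior gray
#' level equals the quadratic MGV model at `hct` (plus optional pixel noise)
#' and the disc's physical area equals the linear surface-area model at
#' `hct`, converted to mm^2 by `area_scale` and scaled proportionally with
#' the spotted volume (the area model describes a 20 uL spot).
#'
#' @param hct hematocrit fraction in (0, 1).
#' @param spot_volume spotted blood volume in uL (area scales as volume/20).
#' @param pixel_size physical pixel size in mm/px.
#' @param image_noise_sd additive Gaussian pixel noise SD in gray levels.
#' @param seed seed for the pixel noise.
#' @param models a [dbs_models()] bundle.
#' @param area_scale mm^2 per surface-area model unit. The default anchors
#'   a 20 uL spot at HCT 0.4 to 113 mm^2 (about 12 mm diameter).
#' @param background background gray level.
#' @param margin_px frame margin around the disc, in pixels.
#' @return An object of class `spot_image`: list with `pixels` (matrix of
#'   gray levels in 0-255) and `pixel_size` (mm/px).
#' @examples
#' img <- generate_spot_image(0.4, seed = 1)
#' dim(img$pixels)
#' @export
generate_spot_image <- function(hct, spot_volume = 20, pixel_size = 0.1,
                                image_noise_sd = 0, seed = 1L,
                                models = dbs_models(),
                                area_scale = 113 / (-0.0397 * 0.4 + 0.0922),
                                background = 255, margin_px = 6) {
  stopifnot(pixel_size > 0, spot_volume > 0)
  if (hct <= 0 || hct >= 1) stop("hct must lie strictly inside (0, 1)")
  area_mm2 <- model_response(models, "sa", hct) * area_scale * spot_volume / 20
  if (area_mm2 <= 0) stop("surface-area model gives non-positive area")
  r_px <- sqrt(area_mm2 / pi) / pixel_size
  half <- ceiling(r_px) + margin_px
  n <- 2L * half + 1L
  ctr <- half + 1L
  gray <- model_response(models, "mgv", hct)

  row_d2 <- (seq_len(n) - ctr)^2
  d2 <- outer(row_d2, row_d2, `+`)
  inside <- d2 <= r_px^2
  px <- matrix(background, n, n)
  px[inside] <- gray
  if (image_noise_sd > 0) {
    px[inside] <- with_local_seed(substream_seed(seed, "image"), {
      px[inside] + stats::rnorm(sum(inside), 0, image_noise_sd)
    })
    px <- pmin(pmax(px, 0), 255)
  }
  spot_image(px, pixel_size)
}

#' Construct a spot image object
#'
#' @param pixels numeric matrix of gray levels in \[0, 255\].
#' @param pixel_size physical pixel size in mm/px.
#' @return Object of class `spot_image`.
#' @export
spot_image <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 8, ncol(pixels) >= 8,
            pixel_size > 0, all(pixels >= 0), all(pixels <= 255))
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "spot_image")
}

#' @export
print.spot_image <- function(x, ...) {
  cat(sprintf("<spot_image> %d x %d px, %.4g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size))
  invisible(x)
}

#' Generate a synthetic conductivity calibration table
#'
#' For each HCT level with a calibration line `volume = slope*cond +
#' intercept`, the noise-free conductivity of a spotted volume is obtained
#' by algebraic inversion, `cond = (volume - intercept)/slope`, and
#' measurement noise is then applied. Under the published intercepts the
#' smallest spotted volumes can invert to negative conductivities; these
#' are kept (they are what the printed algebra implies) and flagged with a
#' warning.
#'
#' @param models a [dbs_models()] bundle (uses `cond_lines`).
#' @param volumes spotted blood volumes in uL, each within 5-40.
#' @param hct_levels HCT levels to include (must have lines in `models`).
#' @param n_replicates replicates per HCT x volume cell.
#' @param noise a [noise_spec()] for the conductivity measurement, or
#'   `"qc"` for the printed per-level values.
#' @param seed master seed.
#' @return data.frame with columns `hct`, `volume`, `replicate`,
#'   `conductivity`.
#' @export
generate_conductivity_table <- function(models = dbs_models(),
                                        volumes = c(5, 10, 20, 30, 40),
                                        hct_levels = models$cond_lines$hct,
                                        n_replicates = 6,
                                        noise = noise_spec(100, 0),
                                        seed = 1L) {
  if (any(volumes < 5 | volumes > 40)) {
    stop("volumes must lie within the 5-40 uL calibration range")
  }
  missing_hct <- setdiff(hct_levels, models$cond_lines$hct)
  if (length(missing_hct)) {
    stop("no conductivity line for HCT level(s): ",
         paste(missing_hct, collapse = ", "))
  }
  grid <- expand.grid(hct = hct_levels, volume = volumes,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$hct, grid$volume, grid$replicate), ]
  i <- match(grid$hct, models$cond_lines$hct)
  cond0 <- (grid$volume - models$cond_lines$intercept[i]) /
    models$cond_lines$slope[i]
  specs <- if (inherits(noise, "noise_spec")) {
    rep(list(noise), nrow(grid))
  } else {
    lapply(grid$hct, function(h) qc_noise_at("cond", h))
  }
  cond <- with_local_seed(substream_seed(seed, "cond"), {
    vapply(seq_len(nrow(grid)),
           function(j) apply_noise(cond0[j], specs[[j]]), numeric(1))
  })
  if (any(cond < 0)) {
    warning(sum(cond < 0), " negative conductivity value(s): small spotted ",
            "volumes fall below the calibration intercept")
  }
  data.frame(hct = grid$hct, volume = grid$volume,
             replicate = grid$replicate, conductivity = cond,
             row.names = NULL)
}

#' Generate a synthetic patient cohort
#'
#' Each patient gets a true HCT drawn uniformly from `hct_range`, a punch
#' blood volume from the punch-volume truth model, and one measured value
#' per modality (MGV, absorbance, extract conductivity) from the forward
#' models plus the corresponding noise. The reference HCT emulates a
#' hematology-analyzer measurement with its own (by default noise-free)
#' error. Conductivity truth uses HCT-interpolated line coefficients.
#'
#' @param n number of patients (> 0).
#' @param hct_range (lo, hi) with 0 < lo < hi < 1.
#' @param models a [dbs_models()] bundle.
#' @param noise named list with optional entries `mgv`, `abs`, `cond`
#'   ([noise_spec()] or `"qc"` for RSD interpolated from the printed QC
#'   precisions, accuracy 100) and `reference` (a [noise_spec()], default
#'   exact).
#' @param cond_curve which conductivity line defines the noise-free punch
#'   conductivity: the pooled `"average"` line (default — the curve the
#'   patient workflow back-calculates with, keeping generation and
#'   estimation consistent) or HCT-interpolated `"hct_specific"` lines.
#'   Under the printed intercepts, punch-scale conductivities can be
#'   negative; they are kept and flagged downstream.
#' @param seed master seed.
#' @return data.frame with columns `patient`, `true_hct`, `reference_hct`,
#'   `mgv`, `abs550`, `conductivity`, `true_punch_volume`.
#' @export
generate_patient_cohort <- function(n = 23, hct_range = c(0.35, 0.46),
                                    models = dbs_models(),
                                    noise = list(mgv = "qc", abs = "qc",
                                                 cond = "qc",
                                                 reference = noise_spec(100, 0)),
                                    cond_curve = c("average", "hct_specific"),
                                    seed = 1L) {
  cond_curve <- match.arg(cond_curve)
  if (n <= 0) stop("n must be positive")
  stopifnot(length(hct_range) == 2, hct_range[1] > 0,
            hct_range[1] < hct_range[2], hct_range[2] < 1)

  true_hct <- with_local_seed(substream_seed(seed, "hct"), {
    stats::runif(n, hct_range[1], hct_range[2])
  })
  v_true <- punch_volume(models, true_hct)

  draw_mod <- function(label, truth, spec_arg, qc_method) {
    specs <- if (inherits(spec_arg, "noise_spec")) {
      rep(list(spec_arg), n)
    } else {
      lapply(true_hct, function(h) {
        noise_spec(100, response_rsd_interp(models, qc_method, h))
      })
    }
    with_local_seed(substream_seed(seed, label), {
      vapply(seq_len(n), function(i) apply_noise(truth[i], specs[[i]]),
             numeric(1))
    })
  }

  ref_spec <- noise$reference %||% noise_spec(100, 0)
  if (cond_curve == "average") {
    sl <- rep(models$cond_pooled[1], n)
    ic <- rep(models$cond_pooled[2], n)
  } else {
    sl <- stats::approx(models$cond_lines$hct, models$cond_lines$slope,
                        xout = true_hct, rule = 2)$y
    ic <- stats::approx(models$cond_lines$hct, models$cond_lines$intercept,
                        xout = true_hct, rule = 2)$y
  }

  # conductivity noise is parameterised in back-calculated volume space
  # (the printed precisions are volume RSDs) and mapped through the line
  cond_spec_arg <- noise$cond %||% "qc"
  v_specs <- if (inherits(cond_spec_arg, "noise_spec")) {
    rep(list(cond_spec_arg), n)
  } else {
    lapply(true_hct, function(h) noise_spec(100, qc_rsd_interp("cond", h)))
  }
  v_meas <- with_local_seed(substream_seed(seed, "cond"), {
    vapply(seq_len(n), function(i) apply_noise(v_true[i], v_specs[[i]]),
           numeric(1))
  })
  conductivity <- (v_meas - ic) / sl

  data.frame(
    patient = seq_len(n),
    true_hct = true_hct,
    reference_hct = draw_mod("reference", true_hct, ref_spec, "abs"),
    mgv = draw_mod("mgv", model_response(models, "mgv", true_hct),
                   noise$mgv %||% "qc", "mgv"),
    abs550 = draw_mod("abs", model_response(models, "abs", true_hct),
                      noise$abs %||% "qc", "abs"),
    conductivity = conductivity,
    true_punch_volume = v_true
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
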