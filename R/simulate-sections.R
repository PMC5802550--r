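#' Configuration for the synthetic organoid-section generator
#'
#' Defines the geometry and statistical structure of a simulated cortical
#' rosette: a circular lumen surrounded by concentric ventricular (VZ),
#' intermediate (IZ) and cortical (CZ) zones. Proliferating cells sit in
#' the VZ annulus in the control phenotype and scatter into IZ and CZ in
#' the disease phenotype; interneurons lie in the CZ with long axes
#' concentrated along the cortical-surface tangent (control) or oriented
#' uniformly (disease).
#'
#' Phenotype presets fill `dispersion_fraction` (0.05 control, 0.5
#' disease) and `orientation_kappa` (8 control, 0 disease) unless these
#' are given explicitly.
#'
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @param phenotype `"control"` or `"disease"`.
#' @param pixel_size_um Micrometres per pixel (default 0.36, at which a
#'   50 px cell body spans 18 um).
#' @param lumen_radius_px,vz_thickness_px,iz_outer_radius_px,cz_outer_radius_px
#'   Concentric zone geometry in pixels; must satisfy
#'   `lumen < lumen + vz < iz_outer < cz_outer`.
#' @param n_proliferating Number of proliferating (Ki67-like) cells.
#' @param dispersion_fraction Fraction in `[0, 1]` of proliferating cells
#'   placed uniformly over IZ and CZ instead of the VZ annulus.
#' @param n_interneurons Number of elongated (calretinin-like) cells.
#' @param orientation_kappa Concentration of interneuron deviation angles
#'   about 0 degrees (tangent-aligned); 0 means uniform on `[0, 90]`.
#' @param cell_body_len_px Mean interneuron body length in pixels
#'   (default 50).
#' @param blob_sigma_px Gaussian radius of a rendered nucleus.
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (on the 0-1 amplitude scale).
#' @param background_level Constant intensity offset (0-1 scale).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              phenotype = c("control", "disease"),
                              pixel_size_um = 0.36,
                              lumen_radius_px = 40,
                              vz_thickness_px = 60,
                              iz_outer_radius_px = 160,
                              cz_outer_radius_px = 230,
                              n_proliferating = 40,
                              dispersion_fraction = NULL,
                              n_interneurons = 38,
                              orientation_kappa = NULL,
                              cell_body_len_px = 50,
                              blob_sigma_px = 2,
                              noise_sd = 0.01,
                              background_level = 0.05) {
  phenotype <- match.arg(phenotype)
  dispersion_fraction <- dispersion_fraction %||%
    switch(phenotype, control = 0.05, disease = 0.5)
  orientation_kappa <- orientation_kappa %||%
    switch(phenotype, control = 8, disease = 0)
  assert_scalar_number(dispersion_fraction, "dispersion_fraction", 0, 1)
  assert_scalar_number(orientation_kappa, "orientation_kappa", 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", 1e-12)
  for (nm in c("n_proliferating", "n_interneurons")) {
    assert_scalar_number(get(nm), nm, 0)
  }
  vz_outer <- lumen_radius_px + vz_thickness_px
  if (!(lumen_radius_px > 0 && vz_thickness_px > 0 &&
        vz_outer < iz_outer_radius_px &&
        iz_outer_radius_px < cz_outer_radius_px)) {
    abort("zone radii must satisfy lumen < lumen + vz < iz_outer < cz_outer")
  }
  structure(
    list(seed = as.integer(seed), phenotype = phenotype,
         pixel_size_um = pixel_size_um,
         lumen_radius_px = lumen_radius_px,
         vz_thickness_px = vz_thickness_px,
         vz_outer_radius_px = vz_outer,
         iz_outer_radius_px = iz_outer_radius_px,
         cz_outer_radius_px = cz_outer_radius_px,
         n_proliferating = as.integer(n_proliferating),
         dispersion_fraction = dispersion_fraction,
         n_interneurons = as.integer(n_interneurons),
         orientation_kappa = orientation_kappa,
         cell_body_len_px = cell_body_len_px,
         blob_sigma_px = blob_sigma_px,
         noise_sd = noise_sd,
         background_level = background_level,
         canvas_px = 2L * ceiling(cz_outer_radius_px) + 41L,
         center = rep(ceiling(cz_outer_radius_px) + 20, 2)),
    class = "simulation_config"
  )
}

# uniform sample over the annulus [r0, r1) around `center`
sample_annulus <- function(n, r0, r1, center) {
  r <- sqrt(runif(n, r0^2, r1^2))
  th <- runif(n, 0, 2 * pi)
  tibble(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

zone_of_radius <- function(r, config) {
  dplyr::case_when(
    r < config$lumen_radius_px ~ "lumen",
    r < config$vz_outer_radius_px ~ "VZ",
    r < config$iz_outer_radius_px ~ "IZ",
    r <= config$cz_outer_radius_px ~ "CZ",
    TRUE ~ "outside"
  )
}

#' Simulate a proliferating-cell point pattern in a rosette section
#'
#' Places `n_proliferating` cell centroids: a fraction
#' `1 - dispersion_fraction` uniformly in the VZ annulus around the lumen
#' (the control-like germinal pattern) and `dispersion_fraction` uniformly
#' over the IZ and CZ annuli (the dispersed, disease-like pattern).
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per cell: `x`, `y` (pixel coordinates),
#'   `zone` (the zone the cell was planted in) and `dispersed` (whether it
#'   was drawn from the dispersed component). The config is attached as
#'   attribute `config`.
#' @export
simulate_rosette_points <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proliferating
  if (n == 0L) {
    out <- tibble(x = double(), y = double(), zone = character(),
                  dispersed = logical())
    attr(out, "config") <- config
    return(out)
  }
  n_disp <- round(config$dispersion_fraction * n)
  out <- with_local_seed(config$seed, {
    vz <- sample_annulus(n - n_disp, config$lumen_radius_px,
                         config$vz_outer_radius_px, config$center)
    dz <- sample_annulus(n_disp, config$vz_outer_radius_px,
                         config$cz_outer_radius_px, config$center)
    dplyr::bind_rows(
      dplyr::mutate(vz, dispersed = FALSE),
      dplyr::mutate(dz, dispersed = TRUE)
    )
  })
  r <- sqrt((out$x - config$center[1])^2 + (out$y - config$center[2])^2)
  out$zone <- zone_of_radius(r, config)
  out <- out[, c("x", "y", "zone", "dispersed")]
  attr(out, "config") <- config
  out
}

#' Cortical-surface curve of the simulated rosette
#'
#' The outer boundary of the cortical zone, discretised as a closed
#' polyline, for use as the reference surface in orientation morphometry.
#'
#' @param config A [simulation_config()].
#' @param n_vertices Number of polyline vertices.
#' @return A [surface_curve()].
#' @export
rosette_surface <- function(config, n_vertices = 180L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  surface_curve(cbind(x = config$center[1] + config$cz_outer_radius_px * cos(th),
                      y = config$center[2] + config$cz_outer_radius_px * sin(th)),
                closed = TRUE)
}

# folded axial deviation angles in degrees on [0, 90]: wrapped normal on the
# doubled-angle circle with sd 1/sqrt(kappa) rad, folded; kappa = 0 -> uniform
sample_deviation_angles <- function(n, kappa) {
  if (kappa <= 0) return(runif(n, 0, 90))
  th2 <- rnorm(n, 0, 1 / sqrt(kappa))
  th2 <- atan2(sin(th2), cos(th2))       # wrap to (-pi, pi]
  abs(th2) / 2 * 180 / pi
}

#' Simulate elongated interneurons along the cortical surface
#'
#' Each cell gets a centroid in the cortical zone, a body length jittered
#' around `cell_body_len_px` (lognormal, 15% coefficient of variation) and
#' a deviation angle from the local surface tangent drawn from a folded
#' wrapped-normal on `[0, 90]` degrees with concentration
#' `orientation_kappa`; `orientation_kappa = 0` gives the uniform
#' (disease-like) distribution. The absolute long-axis angle is the local
#' tangent angle plus a randomly signed deviation.
#'
#' Cell centroids are placed in the cortical band by dart throwing with a
#' minimum centre-to-centre separation (default 0.45 of the body length),
#' which keeps rendered cells from fusing at the densities used; if the
#' rejection budget is exhausted the remaining cells are placed without
#' the separation constraint and a warning is emitted.
#'
#' @param config A [simulation_config()].
#' @param surface A [surface_curve()]; defaults to [rosette_surface()].
#' @param min_separation_px Minimum centroid separation in pixels.
#' @return A tibble with one row per cell: `cell_id`, `x`, `y`,
#'   `body_length_px`, `true_deviation_deg`, `long_axis_deg` (absolute
#'   angle in `[0, 180)`, image convention with y downwards).
#' @export
simulate_interneurons <- function(config, surface = rosette_surface(config),
                                  min_separation_px = 0.45 * config$cell_body_len_px) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_interneurons
  if (n == 0L) {
    return(tibble(cell_id = integer(), x = double(), y = double(),
                  body_length_px = double(), true_deviation_deg = double(),
                  long_axis_deg = double()))
  }
  r0 <- config$iz_outer_radius_px + 0.1 * config$cell_body_len_px
  r1 <- config$cz_outer_radius_px - 0.6 * config$cell_body_len_px
  out <- with_local_seed(config$seed + 1L, {
    xs <- ys <- numeric(0)
    tries <- 0L
    budget <- 300L * n
    while (length(xs) < n && tries < budget) {
      tries <- tries + 1L
      cand <- sample_annulus(1L, r0, r1, config$center)
      if (length(xs) == 0L ||
          min((xs - cand$x)^2 + (ys - cand$y)^2) >= min_separation_px^2) {
        xs <- c(xs, cand$x); ys <- c(ys, cand$y)
      }
    }
    if (length(xs) < n) {
      miss <- n - length(xs)
      warn(sprintf("placed %d of %d cells with min separation %.0f px; %d placed unconstrained",
                   length(xs), n, min_separation_px, miss))
      extra <- sample_annulus(miss, r0, r1, config$center)
      xs <- c(xs, extra$x); ys <- c(ys, extra$y)
    }
    pos <- tibble(x = xs, y = ys)
    len <- config$cell_body_len_px * exp(rnorm(n, 0, 0.15))
    dev <- sample_deviation_angles(n, config$orientation_kappa)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    tangent <- vapply(seq_len(n), function(i) {
      surface_tangent_angle(surface, pos$x[i], pos$y[i])
    }, numeric(1))
    tibble(cell_id = seq_len(n), x = pos$x, y = pos$y,
           body_length_px = len, true_deviation_deg = dev,
           long_axis_deg = (tangent + sgn * dev) %% 180)
  })
  attr(out, "config") <- config
  out
}

#' Simulate a multi-ROI dispersion cohort
#'
#' Generates the point patterns of a full dispersion experiment: a set of
#' ROIs per phenotype group, each an independent rosette section with the
#' group's dispersion fraction. The default design mirrors the study
#' scale of 17 control and 20 disease ROIs with roughly 40 proliferating
#' cells per ROI.
#'
#' @param seed Integer seed; each ROI derives its own sub-seed.
#' @param n_rois Named integer vector: ROIs per group.
#' @param n_cells Cells per ROI.
#' @param dispersion Named numeric vector of per-group dispersion
#'   fractions; defaults to the phenotype presets.
#' @param ... Further arguments passed to [simulation_config()].
#' @return Long tibble with columns `group`, `roi`, `x`, `y`, ready for
#'   [dispersion_experiment()].
#' @export
simulate_dispersion_cohort <- function(seed = 1L,
                                       n_rois = c(control = 17L, disease = 20L),
                                       n_cells = 40L,
                                       dispersion = c(control = 0.05, disease = 0.5),
                                       ...) {
  stopifnot(!is.null(names(n_rois)), all(names(n_rois) %in% names(dispersion)))
  cfgs <- lapply(names(n_rois), function(grp) {
    simulation_config(seed = seed, n_proliferating = n_cells,
                      dispersion_fraction = unname(dispersion[[grp]]), ...)
  })
  names(cfgs) <- names(n_rois)
  with_local_seed(seed, {
    parts <- lapply(names(n_rois), function(grp) {
      cfg <- cfgs[[grp]]
      n_disp <- round(cfg$dispersion_fraction * n_cells)
      do.call(rbind, lapply(seq_len(n_rois[[grp]]), function(i) {
        vz <- sample_annulus(n_cells - n_disp, cfg$lumen_radius_px,
                             cfg$vz_outer_radius_px, cfg$center)
        dz <- sample_annulus(n_disp, cfg$vz_outer_radius_px,
                             cfg$cz_outer_radius_px, cfg$center)
        data.frame(group = grp, roi = sprintf("%s_%02d", grp, i),
                   x = c(vz$x, dz$x), y = c(vz$y, dz$y))
      }))
    })
    as_tibble(do.call(rbind, parts))
  })
}
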