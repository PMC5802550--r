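# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Morphological skeleton of a binary mask (Guo-Hall thinning)
#'
#' Iteratively peels boundary pixels in the two-subiteration Guo-Hall
#' scheme until the shape is reduced to a 1-pixel-wide skeleton that
#' preserves connectivity, branch structure (neurites remain as
#' branches) and line ends, so the skeleton of an elongated bar runs
#' nearly its full length.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return Logical matrix of the same shape containing the skeleton.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask & TRUE
  parity <- 0L
  stuck <- 0L
  repeat {
    parity <- parity + 1L
    # neighbours clockwise from north (image rows increase downwards,
    # the labelling is conventional and only consistency matters)
    p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
    p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
    p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
    p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
    cnum <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
      (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
    n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
    n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
    nmin <- pmin(n1, n2)
    o <- if (parity %% 2L == 1L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
    cond <- m & cnum == 1 & nmin >= 2 & nmin <= 3 & !o
    if (any(cond)) {
      m[cond] <- FALSE
      stuck <- 0L
    } else {
      stuck <- stuck + 1L
      if (stuck >= 2L) break
    }
  }
  m
}

#' Segment elongated cells from a fluorescence channel
#'
#' Threshold (Otsu by default), 8-connected components and an area
#' filter, yielding one pixel mask per cell. Masks are stored cropped to
#' their bounding box with a pixel offset so downstream measurements can
#' recover absolute coordinates.
#'
#' @param image A background-subtracted [channel_image()] of an
#'   interneuron marker (e.g. calretinin).
#' @param params A [detection_params()]; for elongated cells use a large
#'   `max_area_px2`.
#' @return Tibble with one row per cell: `cell_id`, `x`, `y` (centroid,
#'   0-based px), `area_px2` and a `mask` list-column of cropped logical
#'   matrices carrying an `offset = c(x0, y0)` attribute. Zero rows when
#'   nothing is found.
#' @export
segment_cells <- function(image, params = detection_params(smoothing_sigma_px = 0,
                                                           min_area_px2 = 20,
                                                           max_area_px2 = 1e5)) {
  stopifnot(inherits(image, "channel_image"))
  seg <- segment_components(image, params)
  if (is.null(seg$info)) {
    return(tibble(cell_id = integer(), x = double(), y = double(),
                  area_px2 = double(), mask = list()))
  }
  lab <- seg$labels
  masks <- lapply(seg$info$label, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    m <- lab[r0:r1, c0:c1, drop = FALSE] == l
    attr(m, "offset") <- c(x0 = c0 - 1, y0 = r0 - 1)
    m
  })
  tibble(cell_id = seq_len(nrow(seg$info)),
         x = seg$info$x, y = seg$info$y,
         area_px2 = seg$info$area_px2, mask = masks)
}

#' Total cell length from the mask skeleton
#'
#' Skeletonises the mask and sums skeleton adjacencies: 1 px per
#' 4-neighbour step and sqrt(2) px per diagonal step, over all branches,
#' so neurites contribute to the total alongside the cell body. The
#' physical length uses the pixel calibration (at 0.36 um/px a 50 px
#' body measures 18 um).
#'
#' @param mask Logical matrix (a cell mask, cropped or full-frame).
#' @param pixel_size_um Micrometres per pixel.
#' @return Named numeric vector `c(total_length_px = , total_length_um = )`.
#' @export
measure_total_length <- function(mask, pixel_size_um = 0.36) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) abort("empty mask: length undefined")
  s <- skeletonize_mask(mask)
  nr <- nrow(s); nc <- ncol(s)
  horiz <- if (nc > 1) sum(s[, -nc] & s[, -1]) else 0
  vert <- if (nr > 1) sum(s[-nr, ] & s[-1, ]) else 0
  diag1 <- if (nr > 1 && nc > 1) sum(s[-nr, -nc] & s[-1, -1]) else 0
  diag2 <- if (nr > 1 && nc > 1) sum(s[-nr, -1] & s[-1, -nc]) else 0
  len <- horiz + vert + sqrt(2) * (diag1 + diag2)
  c(total_length_px = len, total_length_um = len * pixel_size_um)
}

#' Long-axis orientation of a cell mask
#'
#' Orientation of the principal axis of the mask's pixel-coordinate
#' second central moments, in degrees in `[0, 180)` measured from the +x
#' axis towards +y (image convention, y downwards). Nearly isotropic
#' masks (principal moments equal within `tol`) have no defined long
#' axis and return `NA` so callers can exclude them.
#'
#' @param mask Logical matrix with at least 2 foreground pixels.
#' @param tol Relative eigenvalue-gap tolerance below which the
#'   orientation is flagged undefined.
#' @return Angle in degrees in `[0, 180)`, or `NA_real_` if undefined.
#' @export
fit_long_axis <- function(mask, tol = 1e-3) {
  stopifnot(is.matrix(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2L) abort("mask needs >= 2 pixels for an orientation")
  ys <- idx[, 1] - 1; xs <- idx[, 2] - 1
  mu20 <- mean((xs - mean(xs))^2)
  mu02 <- mean((ys - mean(ys))^2)
  mu11 <- mean((xs - mean(xs)) * (ys - mean(ys)))
  gap <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (gap <= tol * (mu20 + mu02)) return(NA_real_)
  (0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi) %% 180
}

#' Deviation angle between a cell's long axis and the cortical surface
#'
#' The tangent is taken at the surface point nearest the cell centroid
#' (distance ties resolved towards the lowest arc length). The deviation
#' is the undirected angle between the two axes, folded into `[0, 90]`
#' degrees: 0 means tangent-aligned, 90 means radial. Invariant to
#' flipping either the axis or the tangent by 180 degrees.
#'
#' @param long_axis_angle_deg Cell long-axis angle in degrees.
#' @param centroid Length-2 numeric `(x, y)` in pixels.
#' @param surface A [surface_curve()].
#' @return Deviation angle in degrees in `[0, 90]`.
#' @export
deviation_from_surface <- function(long_axis_angle_deg, centroid, surface) {
  stopifnot(inherits(surface, "surface_curve"))
  tangent <- surface_tangent_angle(surface, centroid[1], centroid[2])
  d <- abs(long_axis_angle_deg - tangent) %% 180
  min(d, 180 - d)
}

#' Full morphometry of segmented interneurons
#'
#' Convenience wrapper: [segment_cells()], then per cell the skeleton
#' total length, long-axis orientation and (if a surface is supplied)
#' deviation angle. Cells with undefined orientation get `NA` angles and
#' their count is reported in a message; they are excluded from angle
#' analyses downstream but keep their length.
#'
#' @param image A background-subtracted [channel_image()].
#' @param params A [detection_params()].
#' @param surface Optional [surface_curve()].
#' @return Tibble: `cell_id`, `x`, `y`, `area_px2`, `total_length_px`,
#'   `total_length_um`, `long_axis_deg`, `deviation_deg`.
#' @export
measure_cells <- function(image, params = detection_params(smoothing_sigma_px = 0,
                                                           min_area_px2 = 20,
                                                           max_area_px2 = 1e5),
                          surface = NULL) {
  cells <- segment_cells(image, params)
  if (nrow(cells) == 0L) {
    return(tibble(cell_id = integer(), x = double(), y = double(),
                  area_px2 = double(), total_length_px = double(),
                  total_length_um = double(), long_axis_deg = double(),
                  deviation_deg = double()))
  }
  lens <- vapply(cells$mask, function(m) measure_total_length(m, image$pixel_size_um),
                 numeric(2))
  axes <- vapply(cells$mask, fit_long_axis, numeric(1))
  n_undef <- sum(is.na(axes))
  if (n_undef > 0) {
    inform(sprintf("%d cell(s) with undefined orientation (near-isotropic mask)",
                   n_undef))
  }
  dev <- rep(NA_real_, nrow(cells))
  if (!is.null(surface)) {
    ok <- !is.na(axes)
    dev[ok] <- vapply(which(ok), function(i) {
      deviation_from_surface(axes[i], c(cells$x[i], cells$y[i]), surface)
    }, numeric(1))
  }
  tibble(cell_id = cells$cell_id, x = cells$x, y = cells$y,
         area_px2 = cells$area_px2,
         total_length_px = lens[1, ], total_length_um = lens[2, ],
         long_axis_deg = axes, deviation_deg = dev)
}

#' Cumulative frequency table over fixed bin edges
#'
#' For each edge `e`, the fraction of values `<= e` — the cumulative
#' distribution curves plotted for cell lengths and deviation angles.
#'
#' @param values Non-empty numeric vector of finite values.
#' @param bin_edges Strictly increasing numeric vector of edges.
#' @return Tibble: `edge`, `cum_fraction`.
#' @export
cumulative_frequency <- function(values, bin_edges) {
  if (!length(values)) abort("`values` must be non-empty")
  if (!all(is.finite(values))) abort("`values` must be finite")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing")
  }
  tibble(edge = bin_edges,
         cum_fraction = vapply(bin_edges, function(e) mean(values <= e),
                               numeric(1)))
}

#' Compare a morphometric measure between two cell groups
#'
#' Two-sample Kolmogorov-Smirnov test on the raw per-cell values
#' (lengths or deviation angles), with per-group n, mean and SEM.
#'
#' @param group_a_values,group_b_values Numeric vectors (`n >= 2` each);
#'   `NA`s (undefined orientations) are dropped.
#' @param labels Group labels.
#' @return A [group_comparison].
#' @export
compare_morphology <- function(group_a_values, group_b_values,
                               labels = c("control", "disease")) {
  a <- group_a_values[!is.na(group_a_values)]
  b <- group_b_values[!is.na(group_b_values)]
  if (length(a) < 2L || length(b) < 2L) abort("each group needs n >= 2")
  ks_two_sample(a, b, labels = labels)
}
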