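ZONE_LEVELS <- c("VZ", "IZ", "CZ", "upper_CZ", "basal_cortex", "rosette", "other")

#' Construct a polygonal region of interest
#'
#' An ROI is an ordered, simple (non-self-intersecting) polygon in 0-based
#' pixel coordinates, tagged with a developmental zone. Areas are computed
#' by the shoelace formula; the physical area uses the pixel calibration.
#'
#' @param vertices Two-column matrix or data frame of `(x, y)` pixel
#'   coordinates, at least 3 rows.
#' @param label ROI identifier.
#' @param zone One of `"VZ"`, `"IZ"`, `"CZ"`, `"upper_CZ"`, `"basal_cortex"`,
#'   `"rosette"`, `"other"`.
#' @param pixel_size_um Micrometres per pixel, used for `area_um2`.
#' @return An object of class `roi_polygon` with computed `area_px2` and
#'   `area_um2`.
#' @export
roi_polygon <- function(vertices, label = "roi", zone = "other",
                        pixel_size_um = 0.36) {
  v <- as.matrix(as.data.frame(vertices))
  if (ncol(v) < 2 || nrow(v) < 3) abort("an ROI needs >= 3 (x, y) vertices")
  v <- v[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  zone <- match.arg(zone, ZONE_LEVELS)
  area <- shoelace_area(v[, 1], v[, 2])
  if (area <= 0) abort("ROI polygon has zero area")
  structure(
    list(vertices = v, label = as.character(label), zone = zone,
         area_px2 = area, area_um2 = area * pixel_size_um^2,
         pixel_size_um = pixel_size_um),
    class = "roi_polygon"
  )
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon '%s'> zone %s, %d vertices, %.1f px^2 (%.1f um^2)\n",
              x$label, x$zone, nrow(x$vertices), x$area_px2, x$area_um2))
  invisible(x)
}

# axis-aligned square ROI helper, corner (x0, y0), side in px
square_roi <- function(x0, y0, side, label = "roi", zone = "other",
                       pixel_size_um = 0.36) {
  roi_polygon(cbind(x = c(x0, x0 + side, x0 + side, x0),
                    y = c(y0, y0, y0 + side, y0 + side)),
              label = label, zone = zone, pixel_size_um = pixel_size_um)
}

#' Read and write ROI sets as JSON or flat CSV
#'
#' The JSON schema is a list of objects
#' `{"label": ..., "zone": ..., "vertices": [[x, y], ...]}` with 0-based
#' pixel coordinates. The CSV layout is one row per vertex with columns
#' `label, zone, x, y, vertex_index`.
#'
#' @param path File path (`.json` or `.csv`).
#' @param pixel_size_um Calibration attached to each ROI.
#' @return `read_rois()`: a list of [roi_polygon()]s. `write_rois()`: the
#'   path, invisibly.
#' @export
read_rois <- function(path, pixel_size_um = 0.36) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    return(lapply(raw, function(r) {
      v <- if (is.matrix(r$vertices)) r$vertices else do.call(rbind, r$vertices)
      roi_polygon(v, label = r$label, zone = r$zone %||% "other",
                  pixel_size_um = pixel_size_um)
    }))
  }
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    return(lapply(split(df, df$label), function(d) {
      d <- d[order(d$vertex_index), ]
      roi_polygon(d[, c("x", "y")], label = d$label[1], zone = d$zone[1],
                  pixel_size_um = pixel_size_um)
    }))
  }
  abort(sprintf("unsupported ROI format '%s'", ext))
}

#' @rdname read_rois
#' @param rois List of [roi_polygon()]s.
#' @export
write_rois <- function(rois, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    payload <- lapply(rois, function(r) {
      list(label = r$label, zone = r$zone,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) unname(r$vertices[i, ])))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- dplyr::bind_rows(lapply(rois, function(r) {
      tibble(label = r$label, zone = r$zone,
             x = r$vertices[, 1], y = r$vertices[, 2],
             vertex_index = seq_len(nrow(r$vertices)))
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    abort(sprintf("unsupported ROI format '%s'", ext))
  }
  invisible(path)
}

# logical mask (same shape as image) of pixels whose centers fall strictly
# inside the polygon; pixel (i, j) 0-based has center (x = i, y = j)
roi_pixel_mask <- function(roi, dims) {
  nr <- dims[1]; nc <- dims[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  matrix(point_in_polygon(xs, ys, roi$vertices[, 1], roi$vertices[, 2]),
         nrow = nr, ncol = nc)
}

#' Mean fluorescence intensity within an ROI
#'
#' Implements the ROI fluorescence-intensity measurement protocol: the
#' image must already be background-subtracted and converted to 8-bit
#' grayscale; the measurement is the arithmetic mean over pixels whose
#' centers lie strictly inside the polygon. Optionally the mean is taken
#' over thresholded pixels only (the protocol records thresholded pixel
#' counts but reports means; the default measures all ROI pixels).
#'
#' @param image An 8-bit, background-subtracted [channel_image()].
#' @param roi An [roi_polygon()] fully inside the image.
#' @param thresholded_only If `TRUE`, average only pixels `>= threshold`.
#' @param threshold Intensity threshold used when `thresholded_only`.
#' @return A one-row tibble: `roi_label`, `zone`, `mean_intensity`,
#'   `n_pixels`, `background_subtracted`.
#' @export
mean_roi_intensity <- function(image, roi, thresholded_only = FALSE,
                               threshold = 0) {
  stopifnot(inherits(image, "channel_image"), inherits(roi, "roi_polygon"))
  if (image$bit_depth != 8L) {
    abort("`image` must be 8-bit; apply to_grayscale8() first")
  }
  if (!image$background_subtracted) {
    abort("`image` must be background-subtracted; apply subtract_background() first")
  }
  d <- dim(image$pixels)
  rx <- range(roi$vertices[, 1]); ry <- range(roi$vertices[, 2])
  if (rx[1] < 0 || ry[1] < 0 || rx[2] > d[2] - 1 || ry[2] > d[1] - 1) {
    abort(sprintf("ROI '%s' extends outside the image bounds", roi$label))
  }
  mask <- roi_pixel_mask(roi, d)
  vals <- image$pixels[mask]
  if (length(vals) == 0L) {
    abort(sprintf("ROI '%s' contains no pixel centers (degenerate)", roi$label))
  }
  if (thresholded_only) {
    vals <- vals[vals >= threshold]
    if (length(vals) == 0L) {
      abort(sprintf("ROI '%s' has no pixels above threshold %g", roi$label, threshold))
    }
  }
  tibble(roi_label = roi$label, zone = roi$zone,
         mean_intensity = mean(vals), n_pixels = length(vals),
         background_subtracted = TRUE)
}

#' Sample non-overlapping square ROIs inside a tissue mask
#'
#' Draws `n` axis-aligned square ROIs of the requested physical area,
#' uniformly at random among positions where the square is entirely within
#' the mask, rejecting placements that overlap an earlier ROI. Placement is
#' deterministic given `seed`.
#'
#' @param region_mask Logical matrix (`TRUE` = tissue) in image layout.
#' @param roi_area_um2 Target ROI area in square micrometres (e.g. 1e2,
#'   3e3, 5e3 for the basal-cortex, reelin and TBR1 protocols).
#' @param n Number of ROIs to place.
#' @param pixel_size_um Micrometres per pixel.
#' @param seed Integer seed for the placement RNG.
#' @param zone Zone tag for the sampled ROIs.
#' @param max_tries Rejection-sampling budget before giving up.
#' @return List of `n` [roi_polygon()] squares.
#' @export
sample_random_rois <- function(region_mask, roi_area_um2, n, pixel_size_um,
                               seed = 1L, zone = "other", max_tries = 2000L * max(n, 1L)) {
  stopifnot(is.matrix(region_mask), is.logical(region_mask))
  if (!any(region_mask)) abort("`region_mask` is empty")
  if (n == 0L) return(list())
  side <- max(1L, round(sqrt(roi_area_um2) / pixel_size_um))
  nr <- nrow(region_mask); nc <- ncol(region_mask)
  if (side > nc || side > nr) {
    abort(sprintf("ROI side %d px exceeds the mask extent", side))
  }
  # valid anchors: top-left corners whose full square is inside the mask
  ok <- matrix(FALSE, nr, nc)
  cs <- apply(region_mask, 2, cumsum)                # column prefix sums
  rs <- t(apply(cs, 1, cumsum))                      # 2D prefix sums
  at <- function(i, j) ifelse(i < 1 | j < 1, 0, rs[cbind(pmax(i, 1), pmax(j, 1))])
  placed <- list()
  taken <- matrix(FALSE, nr, nc)
  with_local_seed(seed, {
    tries <- 0L
    while (length(placed) < n && tries < max_tries) {
      tries <- tries + 1L
      i0 <- sample.int(nr - side + 1L, 1L)           # row (y+1)
      j0 <- sample.int(nc - side + 1L, 1L)           # col (x+1)
      i1 <- i0 + side - 1L; j1 <- j0 + side - 1L
      full <- at(i1, j1) - at(i0 - 1L, j1) - at(i1, j0 - 1L) + at(i0 - 1L, j0 - 1L)
      if (full < side * side) next
      if (any(taken[i0:i1, j0:j1])) next
      taken[i0:i1, j0:j1] <- TRUE
      placed[[length(placed) + 1L]] <-
        square_roi(j0 - 1L, i0 - 1L, side,
                   label = sprintf("roi_%02d", length(placed) + 1L),
                   zone = zone, pixel_size_um = pixel_size_um)
    }
  })
  if (length(placed) < n) {
    abort(sprintf(
      "could only place %d of %d non-overlapping %dx%d px ROIs within the mask",
      length(placed), n, side, side))
  }
  placed
}
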