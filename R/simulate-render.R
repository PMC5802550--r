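# draw a 1 px wide polyline into `img` (matrix, [row=y, col=x], 0-based coords)
draw_polyline <- function(img, xs, ys, value = 1) {
  for (k in seq_len(length(xs) - 1L)) {
    len <- sqrt((xs[k + 1] - xs[k])^2 + (ys[k + 1] - ys[k])^2)
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.4)))
    px <- round(xs[k] + t * (xs[k + 1] - xs[k])) + 1L
    py <- round(ys[k] + t * (ys[k + 1] - ys[k])) + 1L
    keep <- px >= 1 & px <= ncol(img) & py >= 1 & py <= nrow(img)
    img[cbind(py[keep], px[keep])] <- pmax(img[cbind(py[keep], px[keep])], value)
  }
  img
}

# add a capsule (segment dilated to half-width w) of intensity 1
draw_capsule <- function(img, x0, y0, x1, y1, halfwidth) {
  pad <- ceiling(halfwidth) + 1L
  cx <- max(1L, floor(min(x0, x1)) - pad):min(ncol(img), ceiling(max(x0, x1)) + pad + 1L)
  cy <- max(1L, floor(min(y0, y1)) - pad):min(nrow(img), ceiling(max(y0, y1)) + pad + 1L)
  gx <- rep(cx - 1L, each = length(cy))
  gy <- rep(cy - 1L, times = length(cx))
  d2 <- dist2_to_segment(gx, gy, x0, y0, x1, y1)$d2
  hit <- d2 <= halfwidth^2
  idx <- cbind(gy[hit] + 1L, gx[hit] + 1L)
  img[idx] <- pmax(img[idx], 1)
  img
}

#' Render simulated objects into a fluorescence channel image
#'
#' Point patterns (nuclei) are rendered as Gaussian blobs of radius
#' `blob_sigma_px`; interneurons (rows carrying `long_axis_deg` and
#' `body_length_px`) as elongated capsule bodies with, optionally, two
#' thin polyline neurites extending from the body ends. A constant
#' background and Gaussian read noise are added and intensities are
#' clipped at zero. The result is on the 16-bit scale.
#'
#' @param objects Tibble of points (`x`, `y`) or of interneurons
#'   (`x`, `y`, `body_length_px`, `long_axis_deg`), as produced by
#'   [simulate_rosette_points()] / [simulate_interneurons()].
#' @param config A [simulation_config()]; supplies the canvas size,
#'   blob radius, background level and noise.
#' @param channel Channel label for the output image.
#' @param neurites Render two neurites per cell (ignored for points).
#' @param body_halfwidth_px Capsule half-width in pixels.
#' @return A [channel_image()] (16-bit scale).
#' @export
render_channel <- function(objects, config, channel = "Ki67",
                           neurites = TRUE, body_halfwidth_px = 3) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(objects))
  side <- config$canvas_px
  img <- matrix(0, side, side)
  is_cells <- all(c("long_axis_deg", "body_length_px") %in% names(objects))
  if (nrow(objects) > 0) {
    margin <- if (is_cells) max(objects$body_length_px) else 4 * config$blob_sigma_px
    bad <- which(objects$x < 0 | objects$x > side - 1 |
                   objects$y < 0 | objects$y > side - 1)
    if (length(bad)) {
      abort(sprintf("objects outside the %dx%d canvas: rows %s",
                    side, side, paste(head(bad, 10), collapse = ", ")))
    }
  }
  if (!is_cells && nrow(objects) > 0) {
    s <- config$blob_sigma_px
    w <- ceiling(4 * s)
    for (i in seq_len(nrow(objects))) {
      x0 <- objects$x[i]; y0 <- objects$y[i]
      cx <- max(1L, floor(x0) - w):min(side, ceiling(x0) + w + 1L)
      cy <- max(1L, floor(y0) - w):min(side, ceiling(y0) + w + 1L)
      gx <- rep(cx - 1L, each = length(cy))
      gy <- rep(cy - 1L, times = length(cx))
      val <- exp(-((gx - x0)^2 + (gy - y0)^2) / (2 * s^2))
      idx <- cbind(gy + 1L, gx + 1L)
      img[idx] <- img[idx] + val
    }
  }
  if (is_cells && nrow(objects) > 0) {
    img <- with_local_seed(config$seed + 2L, {
      for (i in seq_len(nrow(objects))) {
        th <- objects$long_axis_deg[i] * pi / 180
        hx <- cos(th) * objects$body_length_px[i] / 2
        hy <- sin(th) * objects$body_length_px[i] / 2
        x0 <- objects$x[i] - hx; y0 <- objects$y[i] - hy
        x1 <- objects$x[i] + hx; y1 <- objects$y[i] + hy
        img <- draw_capsule(img, x0, y0, x1, y1, body_halfwidth_px)
        if (neurites) {
          for (end in list(c(x0, y0, th + pi), c(x1, y1, th))) {
            nlen <- 0.35 * objects$body_length_px[i] * runif(1, 0.7, 1.3)
            nth <- end[3] + runif(1, -0.25, 0.25)    # up to ~14 deg off-axis
            img <- draw_polyline(img,
                                 c(end[1], end[1] + nlen * cos(nth)),
                                 c(end[2], end[2] + nlen * sin(nth)))
          }
        }
      }
      img
    })
  }
  img <- img + config$background_level
  if (config$noise_sd > 0) {
    img <- img + with_local_seed(config$seed + 3L,
                                 matrix(rnorm(side * side, 0, config$noise_sd),
                                        side, side))
  }
  img <- pmax(pmin(img, 1), 0)
  channel_image(img * 65535, channel = channel, bit_depth = 16,
                pixel_size_um = config$pixel_size_um)
}
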