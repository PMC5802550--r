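#' Parameters for nucleus/cell detection
#'
#' Controls the detection pipeline: Gaussian smoothing, a global threshold
#' (Otsu on the image histogram or a fixed value), connected components
#' with 8-connectivity, and an area filter that discards debris below
#' `min_area_px2` and clumps above `max_area_px2`.
#'
#' @param smoothing_sigma_px Gaussian smoothing sigma in pixels (0 = none).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Intensity threshold when `threshold_method =
#'   "fixed"` (on the image's own intensity scale).
#' @param min_area_px2,max_area_px2 Component area bounds in px^2, with
#'   `0 < min < max`.
#' @return A `detection_params` list.
#' @export
detection_params <- function(smoothing_sigma_px = 1,
                             threshold_method = c("otsu", "fixed"),
                             fixed_threshold = NULL,
                             min_area_px2 = 4,
                             max_area_px2 = 1000) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" && is.null(fixed_threshold)) {
    abort("`fixed_threshold` is required when threshold_method = 'fixed'")
  }
  if (!(min_area_px2 > 0 && min_area_px2 < max_area_px2)) {
    abort("need 0 < min_area_px2 < max_area_px2")
  }
  assert_scalar_number(smoothing_sigma_px, "smoothing_sigma_px", 0)
  structure(list(smoothing_sigma_px = smoothing_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_px2 = min_area_px2,
                 max_area_px2 = max_area_px2),
            class = "detection_params")
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels that touch only diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  lab <- t(EBImage::imageData(lab))
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) with (i+1, j+1), and (i+1, j) with (i, j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                          pairs[, 1] != pairs[, 2], , drop = FALSE])
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
    roots <- vapply(seq_len(nlab), find, integer(1))
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0] <- dense[lab[lab > 0]]
  }
  lab
}

# global threshold per params; Otsu is computed on the image's own range so
# detection is invariant to adding a constant offset
image_threshold <- function(pixels, params) {
  if (params$threshold_method == "fixed") return(params$fixed_threshold)
  rg <- range(pixels)
  if (diff(rg) == 0) return(Inf)  # flat image: nothing above threshold
  as.numeric(EBImage::otsu(EBImage::Image(t(pixels)), range = rg))
}

# smoothing + threshold + 8-connected components + area filter
segment_components <- function(image, params) {
  px <- image$pixels
  if (params$smoothing_sigma_px > 0) {
    px <- t(EBImage::imageData(
      EBImage::gblur(EBImage::Image(t(px)), sigma = params$smoothing_sigma_px)))
  }
  thr <- image_threshold(px, params)
  mask <- px > thr
  if (!any(mask)) return(list(labels = matrix(0L, nrow(px), ncol(px)), info = NULL))
  lab <- label_components8(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area_px2 & areas <= params$max_area_px2)
  idx <- which(lab > 0)
  l <- lab[idx]
  sel <- l %in% keep
  idx <- idx[sel]; l <- l[sel]
  if (!length(idx)) return(list(labels = matrix(0L, nrow(px), ncol(px)), info = NULL))
  nr <- nrow(px)
  ys <- (idx - 1L) %% nr          # 0-based row
  xs <- (idx - 1L) %/% nr         # 0-based col
  info <- tibble(
    label = sort(unique(l)),
    x = as.numeric(tapply(xs, l, mean)),
    y = as.numeric(tapply(ys, l, mean)),
    area_px2 = as.numeric(tapply(l, l, length))
  )
  newlab <- matrix(0L, nrow(px), ncol(px))
  newlab[idx] <- match(l, info$label)
  info$label <- seq_len(nrow(info))
  list(labels = newlab, info = info)
}

#' Detect labelled nuclei in a fluorescence channel
#'
#' Pipeline: Gaussian smoothing, global threshold (Otsu by default),
#' 8-connected components, area filter, centroid per surviving component.
#' Components touching the image border are retained. If an ROI is given,
#' only centroids strictly inside its polygon are returned.
#'
#' @param image A background-subtracted [channel_image()].
#' @param params A [detection_params()].
#' @param roi Optional [roi_polygon()] restricting the output.
#' @return Tibble of centroids: `x`, `y` (0-based px), `area_px2`,
#'   `channel` and, when `roi` is given, `roi_label`. An all-flat image
#'   yields zero rows.
#' @export
detect_nuclei <- function(image, params = detection_params(), roi = NULL) {
  stopifnot(inherits(image, "channel_image"), inherits(params, "detection_params"))
  seg <- segment_components(image, params)
  if (is.null(seg$info)) {
    out <- tibble(x = double(), y = double(), area_px2 = double(),
                  channel = character())
  } else {
    out <- dplyr::mutate(seg$info[, c("x", "y", "area_px2")],
                         channel = image$channel)
  }
  if (!is.null(roi)) {
    keep <- point_in_polygon(out$x, out$y, roi$vertices[, 1], roi$vertices[, 2])
    out <- out[keep, , drop = FALSE]
    out$roi_label <- rep(roi$label, nrow(out))
  }
  out
}

#' Count detected cells inside an ROI
#'
#' Counts points whose coordinates fall strictly inside the polygon
#' (boundary points excluded, consistent with the pixel-center rule).
#' This is the per-ROI cell density `d` = number of cells per ROI.
#'
#' @param points Data frame with `x`, `y` columns.
#' @param roi An [roi_polygon()].
#' @return Integer count.
#' @export
count_in_roi <- function(points, roi) {
  stopifnot(is.data.frame(points), inherits(roi, "roi_polygon"))
  if (nrow(points) == 0L) return(0L)
  sum(point_in_polygon(points$x, points$y,
                       roi$vertices[, 1], roi$vertices[, 2]))
}

#' Fraction of DAPI nuclei positive for a second marker
#'
#' A nucleus is marker-positive when the thresholded marker channel is
#' above threshold at a sufficient fraction of the pixels of a disk
#' around the nucleus centroid. Returns the percentage of positive
#' nuclei among DAPI nuclei in the ROI, as in TBR1+/DAPI and
#' nFGFR1+/DAPI quantifications.
#'
#' @param dapi_points Data frame of nucleus centroids (`x`, `y`).
#' @param marker_image [channel_image()] for the marker channel.
#' @param marker_params [detection_params()] supplying the threshold rule
#'   for the marker channel.
#' @param roi Optional [roi_polygon()]; only nuclei inside it are scored.
#' @param disk_radius_px Radius of the nucleus disk (default 4 px).
#' @param coverage_fraction Minimum above-threshold fraction of the disk
#'   for a nucleus to count as positive (default 0.5).
#' @return Percentage in `[0, 100]`.
#' @export
positive_fraction <- function(dapi_points, marker_image,
                              marker_params = detection_params(),
                              roi = NULL, disk_radius_px = 4,
                              coverage_fraction = 0.5) {
  stopifnot(is.data.frame(dapi_points), inherits(marker_image, "channel_image"))
  pts <- dapi_points
  if (!is.null(roi)) {
    keep <- point_in_polygon(pts$x, pts$y, roi$vertices[, 1], roi$vertices[, 2])
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) == 0L) abort("no DAPI nuclei in the ROI: positive fraction undefined")
  thr <- image_threshold(marker_image$pixels, marker_params)
  above <- marker_image$pixels > thr
  nr <- nrow(above); nc <- ncol(above)
  r <- disk_radius_px
  offs <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  pos <- vapply(seq_len(nrow(pts)), function(i) {
    xs <- round(pts$x[i]) + offs$dx
    ys <- round(pts$y[i]) + offs$dy
    keep <- xs >= 0 & xs < nc & ys >= 0 & ys < nr
    if (!any(keep)) return(FALSE)
    mean(above[cbind(ys[keep] + 1L, xs[keep] + 1L)]) >= coverage_fraction
  }, logical(1))
  100 * mean(pos)
}

#' Count double-labelled cells by nearest-neighbour matching
#'
#' Matches centroids detected in two channels one-to-one by greedy
#' nearest-neighbour pairing (candidate pairs sorted by distance,
#' closest first) within `match_radius_px`. Used for co-labelling counts
#' such as BrdU+/Pan-Neu+ per ROI. Greedy matching is deterministic and
#' adequate at the densities involved, though not guaranteed optimal.
#'
#' @param points_a,points_b Data frames of centroids (`x`, `y`).
#' @param match_radius_px Maximum centre-to-centre distance for a match.
#' @return One-row tibble: `n_a`, `n_b`, `n_both`, `pct_a_double`,
#'   `pct_b_double` (percent of each channel's cells that are matched).
#' @export
double_label_counts <- function(points_a, points_b, match_radius_px = 5) {
  assert_scalar_number(match_radius_px, "match_radius_px", 1e-12)
  na <- nrow(points_a); nb <- nrow(points_b)
  n_both <- 0L
  if (na > 0 && nb > 0) {
    dx <- outer(points_a$x, points_b$x, "-")
    dy <- outer(points_a$y, points_b$y, "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= match_radius_px, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      used_a <- logical(na); used_b <- logical(nb)
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          used_a[i] <- TRUE; used_b[j] <- TRUE
          n_both <- n_both + 1L
        }
      }
    }
  }
  tibble(n_a = na, n_b = nb, n_both = n_both,
         pct_a_double = if (na > 0) 100 * n_both / na else NA_real_,
         pct_b_double = if (nb > 0) 100 * n_both / nb else NA_real_)
}
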