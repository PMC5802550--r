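#' Construct a cortical-surface curve
#'
#' A polyline (open or closed) tracing the cortical surface in pixel
#' coordinates, with an arc-length parameterization. The curve supplies,
#' for any query point, the nearest curve point and the unit tangent
#' there; deviation angles of cell long axes are measured against that
#' tangent.
#'
#' @param vertices Two-column matrix or data frame of ordered `(x, y)`
#'   vertices; at least 2, consecutive vertices distinct.
#' @param closed If `TRUE` the last vertex connects back to the first.
#' @return An object of class `surface_curve`.
#' @export
surface_curve <- function(vertices, closed = FALSE) {
  v <- as.matrix(as.data.frame(vertices))[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  if (nrow(v) < 2) abort("a surface curve needs >= 2 vertices")
  if (isTRUE(closed)) v <- rbind(v, v[1, ])
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  if (any(seg == 0)) abort("consecutive surface vertices must be distinct")
  structure(
    list(vertices = v, closed = isTRUE(closed),
         arc_length = c(0, cumsum(seg))),
    class = "surface_curve"
  )
}

#' @export
print.surface_curve <- function(x, ...) {
  cat(sprintf("<surface_curve> %d vertices, length %.1f px%s\n",
              nrow(x$vertices), max(x$arc_length),
              if (x$closed) ", closed" else ""))
  invisible(x)
}

# Nearest point on the curve to (px, py): returns the segment index, the
# arc-length, and the squared distance. All segments are evaluated in one
# vectorised pass; ties in distance are broken towards the lowest
# arc-length, deterministically.
surface_nearest <- function(surface, px, py) {
  v <- surface$vertices
  n <- nrow(v)
  x1 <- v[-n, 1]; y1 <- v[-n, 2]
  dx <- v[-1, 1] - x1; dy <- v[-1, 2] - y1
  len2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  d2 <- (px - qx)^2 + (py - qy)^2
  s <- surface$arc_length[-n] + t * (surface$arc_length[-1] - surface$arc_length[-n])
  cand <- which(d2 <= min(d2) + 1e-12)
  k <- cand[which.min(s[cand])]
  list(d2 = d2[k], s = s[k], seg = k, t = t[k])
}

# axial tangent angle (degrees in [0, 180)) at the curve point nearest (px, py)
surface_tangent_angle <- function(surface, px, py) {
  hit <- surface_nearest(surface, px, py)
  v <- surface$vertices
  dx <- v[hit$seg + 1, 1] - v[hit$seg, 1]
  dy <- v[hit$seg + 1, 2] - v[hit$seg, 2]
  (atan2(dy, dx) * 180 / pi) %% 180
}
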