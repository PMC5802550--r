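# Internal geometry and validation helpers shared across modules.

# Even-odd (ray casting) point-in-polygon test, vectorised over query points.
# Returns TRUE for points strictly inside; points exactly on an edge follow
# the crossing rule of the cast ray and are treated as outside by the callers
# that need a strict convention (pixel centers on the boundary are excluded).
point_in_polygon <- function(px, py, vx, vy) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3)
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    # edge (vx[j], vy[j]) -> (vx[i], vy[i]); count crossings of the
    # horizontal ray extending in +x from each query point
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace area of a simple polygon (absolute value, in px^2).
shoelace_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

# Squared distance from points (px, py) to the segment (x1,y1)-(x2,y2),
# plus the parameter t in [0,1] of the nearest point along the segment.
dist2_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- x1 + t * dx
  qy <- y1 + t * dy
  list(d2 = (px - qx)^2 + (py - qy)^2, t = t, qx = qx, qy = qy)
}

# All randomness in the package flows through this helper: the caller's seed
# is applied locally and the global RNG state is restored on exit.
with_local_seed <- function(seed, code) {
  force(seed)
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}
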