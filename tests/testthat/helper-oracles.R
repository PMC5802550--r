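# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, textbook formulas.

# minimum spanning-tree total weight by exhaustive enumeration over all
# (n-1)-edge subsets, cheapest first (n <= 7 keeps this tractable)
oracle_mst_weight <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, n <= 7)
  pairs <- utils::combn(n, 2)
  w <- sqrt((x[pairs[1, ]] - x[pairs[2, ]])^2 + (y[pairs[1, ]] - y[pairs[2, ]])^2)
  subsets <- utils::combn(ncol(pairs), n - 1)
  total <- colSums(matrix(w[subsets], nrow = n - 1))
  ord <- order(total)
  for (k in ord) {
    sel <- subsets[, k]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged <- 0L
    for (e in sel) {
      a <- find(pairs[1, e]); b <- find(pairs[2, e])
      if (a != b) { parent[a] <- b; merged <- merged + 1L }
    }
    if (merged == n - 1L) return(total[k])  # spanning; cheapest by order
  }
  stop("no spanning subset found")
}

# two-sample KS statistic as the sup of |ECDF_a - ECDF_b| over the merged grid
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}

# textbook Pearson correlation, naive loop form
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  unname(num / sqrt(dx * dy))
}

# balanced two-way ANOVA F statistics from explicit sums of squares
oracle_two_way_F <- function(y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  n <- length(y)
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  nab <- table(a, b)
  ssa <- sum(table(a) * (ma - gm)^2)
  ssb <- sum(table(b) * (mb - gm)^2)
  ssab <- sum(nab * (mab - outer(ma, rep(1, nlevels(b))) -
                       outer(rep(1, nlevels(a)), mb) + gm)^2)
  sse <- sum((y - mab[cbind(a, b)])^2)
  dfa <- nlevels(a) - 1; dfb <- nlevels(b) - 1
  dfab <- dfa * dfb; dfe <- n - nlevels(a) * nlevels(b)
  c(A = (ssa / dfa) / (sse / dfe),
    B = (ssb / dfb) / (sse / dfe),
    AB = (ssab / dfab) / (sse / dfe))
}

# a small constant-intensity 8-bit background-subtracted test image
flat_image8 <- function(value, nr = 20, nc = 20, channel = "test") {
  img <- channel_image(matrix(value, nr, nc), channel = channel, bit_depth = 8)
  img$background_subtracted <- TRUE
  img
}
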