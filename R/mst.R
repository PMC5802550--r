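#' Euclidean minimum spanning tree of a cell point pattern
#'
#' Builds the MST of the complete graph on cell centroids using Prim's
#' algorithm with squared-distance keys. The total edge weight is the
#' global minimum; when several spanning trees tie, the edge set returned
#' is the one reached by scanning vertices in index order (lowest index
#' first), which is deterministic. Duplicate points are allowed and yield
#' zero-length edges.
#'
#' @param points Data frame of cell centroids with `x`, `y` columns and
#'   at least 2 rows; coordinates must be finite.
#' @return Tibble of the `n - 1` tree edges: `from`, `to` (row indices of
#'   `points`, `from < to`) and `length_px`.
#' @export
mst_edges <- function(points) {
  stopifnot(is.data.frame(points))
  n <- nrow(points)
  if (n < 2L) abort("an MST needs at least 2 points")
  x <- points$x; y <- points$y
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("coordinates must be finite")
  in_tree <- logical(n)
  key <- rep(Inf, n)       # squared distance to the growing tree
  parent <- rep(NA_integer_, n)
  key[1] <- 0
  for (k in seq_len(n)) {
    u <- which(!in_tree)[which.min(key[!in_tree])]
    in_tree[u] <- TRUE
    d2 <- (x - x[u])^2 + (y - y[u])^2
    upd <- !in_tree & d2 < key
    key[upd] <- d2[upd]
    parent[upd] <- u
  }
  v <- which(!is.na(parent))
  tibble(from = pmin(v, parent[v]), to = pmax(v, parent[v]),
         length_px = sqrt((x[v] - x[parent[v]])^2 + (y[v] - y[parent[v]])^2))
}

#' Bin MST edge lengths into fixed-width distance bins
#'
#' Half-open bins `[0, w), [w, 2w), ...` with 1-based bin labels: bin 1
#' holds edges of 0 up to (excluding) `w` pixels, bin 2 of `w` up to `2w`,
#' and so on, so an edge of exactly `w` pixels falls in bin 2. Trailing
#' empty bins are trimmed.
#'
#' @param edge_lengths Numeric vector of non-negative lengths (px).
#' @param bin_width_px Bin width in pixels (default 5).
#' @return Integer vector of bin counts (possibly length 0).
#' @export
bin_edge_lengths <- function(edge_lengths, bin_width_px = 5) {
  assert_scalar_number(bin_width_px, "bin_width_px", 1e-12)
  if (length(edge_lengths) == 0L) return(integer(0))
  if (any(edge_lengths < 0)) abort("edge lengths must be non-negative")
  tabulate(floor(edge_lengths / bin_width_px) + 1L)
}

#' Summarise one ROI's point pattern by its MST
#'
#' @param points Data frame of centroids (`x`, `y`), `>= 2` rows.
#' @param roi_label Label carried through to outputs.
#' @param bin_width_px Width of the MST distance bins (default 5 px).
#' @return An object of class `mst_summary`: `roi_label`, `n_points`,
#'   `edge_lengths_px`, `bin_counts`, `bin_width_px`, `mean_edge_px`.
#' @export
mst_summary <- function(points, roi_label = "roi", bin_width_px = 5) {
  edges <- mst_edges(points)
  structure(
    list(roi_label = roi_label, n_points = nrow(points),
         edge_lengths_px = edges$length_px,
         bin_counts = bin_edge_lengths(edges$length_px, bin_width_px),
         bin_width_px = bin_width_px,
         mean_edge_px = mean(edges$length_px)),
    class = "mst_summary"
  )
}

#' @export
print.mst_summary <- function(x, ...) {
  cat(sprintf("<mst_summary '%s'> %d cells, %d edges, mean edge %.2f px, %d bins of %g px\n",
              x$roi_label, x$n_points, length(x$edge_lengths_px),
              x$mean_edge_px, length(x$bin_counts), x$bin_width_px))
  invisible(x)
}

#' @method tidy mst_summary
#' @export
tidy.mst_summary <- function(x, ...) {
  nb <- length(x$bin_counts)
  tibble(roi_label = x$roi_label, bin = seq_len(nb),
         lower_px = (seq_len(nb) - 1) * x$bin_width_px,
         upper_px = seq_len(nb) * x$bin_width_px,
         frequency = as.numeric(x$bin_counts))
}

#' Run the MST dispersion analysis over grouped ROIs
#'
#' For every ROI: MST over its cell centroids and edge-length binning;
#' bins are zero-padded to the experiment-wide maximum bin so groups are
#' directly comparable. ROIs with fewer than 2 cells carry no MST and are
#' excluded with a warning (their labels are recorded in the `excluded`
#' attribute).
#'
#' @param points Long data frame of cell centroids with columns `group`,
#'   `roi`, `x`, `y` (one row per cell).
#' @param bin_width_px MST distance bin width (default 5 px).
#' @param normalize If `TRUE`, per-ROI bin counts are divided by the
#'   ROI's edge count (`n - 1`) so ROIs of different cell number weigh
#'   equally.
#' @return Tibble with one row per (group, ROI, bin): `group`,
#'   `roi_label`, `bin`, `frequency`, plus attributes `group_means`
#'   (per-group per-bin mean frequency), `roi_stats` (per-ROI `n_points`
#'   and `mean_edge_px`) and `excluded`.
#' @export
dispersion_experiment <- function(points, bin_width_px = 5, normalize = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("group", "roi", "x", "y") %in% names(points)))
  split_pts <- split(points, list(points$group, points$roi), drop = TRUE, sep = "\r")
  small <- vapply(split_pts, nrow, integer(1)) < 2L
  if (any(small)) {
    warn(sprintf("excluding %d ROI(s) with fewer than 2 cells: %s",
                 sum(small),
                 paste(sub("\r", "/", names(split_pts)[small]), collapse = ", ")))
  }
  split_pts <- split_pts[!small]
  if (!length(split_pts)) abort("no ROI with >= 2 cells")
  sums <- lapply(split_pts, function(d) {
    mst_summary(d, roi_label = d$roi[1], bin_width_px = bin_width_px)
  })
  max_bin <- max(vapply(sums, function(s) length(s$bin_counts), integer(1)))
  nroi <- length(sums)
  grp <- vapply(split_pts, function(d) as.character(d$group[1]), character(1))
  freq_mat <- vapply(sums, function(s) {
    counts <- c(s$bin_counts, rep(0L, max_bin - length(s$bin_counts)))
    if (normalize) counts / length(s$edge_lengths_px) else as.numeric(counts)
  }, numeric(max_bin))
  freq_mat <- matrix(freq_mat, nrow = max_bin)
  rows <- tibble(
    group = rep(grp, each = max_bin),
    roi_label = rep(vapply(sums, function(s) s$roi_label, character(1)),
                    each = max_bin),
    bin = rep(seq_len(max_bin), times = nroi),
    frequency = as.vector(freq_mat)
  )
  attr(rows, "group_means") <- rows |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean_frequency = mean(.data$frequency), .groups = "drop")
  attr(rows, "roi_stats") <- tibble(
    group = grp,
    roi_label = vapply(sums, function(s) s$roi_label, character(1)),
    n_points = vapply(sums, function(s) s$n_points, numeric(1)),
    mean_edge_px = vapply(sums, function(s) s$mean_edge_px, numeric(1))
  )
  attr(rows, "excluded") <- sub("\r", "/", names(small)[small])
  attr(rows, "bin_width_px") <- bin_width_px
  rows
}

#' Test phenotype-by-distance interaction in MST dispersion
#'
#' Two-way ANOVA on the long-format dispersion table with factors
#' phenotype group and MST distance bin and response the per-ROI bin
#' frequency (ROIs are the replicate units). A significant
#' group-by-bin interaction indicates that the edge-length distribution
#' differs between phenotypes, i.e. dispersion of the proliferating
#' cells. Sums of squares are Type II (the design is typically
#' unbalanced in ROI counts).
#'
#' @param table Output of [dispersion_experiment()].
#' @return A [group_comparison] from [two_way_anova()], with effects
#'   `group`, `bin` and `group:bin`.
#' @export
compare_dispersion <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("group", "bin", "frequency") %in% names(table)))
  if (length(unique(table$group)) < 2L) abort("need >= 2 phenotype groups")
  if (length(unique(table$bin)) < 2L) abort("need >= 2 distance bins")
  two_way_anova(table$frequency, table$group, table$bin,
                names = c("group", "bin"))
}
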