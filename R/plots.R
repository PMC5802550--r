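#' Plot a simulated rosette point pattern
#'
#' Cell centroids coloured by zone, with the zone boundary circles.
#'
#' @param points Output of [simulate_rosette_points()].
#' @return A ggplot object.
#' @export
plot_rosette <- function(points) {
  cfg <- attr(points, "config")
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$x, y = .data$y,
                                            colour = .data$zone)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "zone") +
    ggplot2::theme_minimal()
  if (!is.null(cfg)) {
    th <- seq(0, 2 * pi, length.out = 181)
    rings <- dplyr::bind_rows(lapply(
      c(cfg$lumen_radius_px, cfg$vz_outer_radius_px,
        cfg$iz_outer_radius_px, cfg$cz_outer_radius_px),
      function(r) tibble(x = cfg$center[1] + r * cos(th),
                         y = cfg$center[2] + r * sin(th), r = r)))
    p <- p + ggplot2::geom_path(data = rings,
                                ggplot2::aes(group = .data$r),
                                colour = "grey60", inherit.aes = FALSE,
                                mapping = ggplot2::aes(x = .data$x, y = .data$y,
                                                       group = .data$r))
  }
  p
}

#' Plot MST distance-bin frequencies by group
#'
#' Per-group mean frequency per distance bin with SEM error bars — the
#' binned MST edge-length histogram used to compare phenotypes.
#'
#' @param table Output of [dispersion_experiment()].
#' @return A ggplot object.
#' @export
plot_mst_bins <- function(table) {
  w <- attr(table, "bin_width_px") %||% 5
  summ <- table |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(mean = mean(.data$frequency),
                     sem = sd(.data$frequency) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::labs(x = sprintf("MST distance bin (%g px each)", w),
                  y = "mean frequency per ROI", fill = "phenotype") +
    ggplot2::theme_minimal()
}

#' Plot cumulative frequency curves for two groups
#'
#' @param group_a_values,group_b_values Numeric vectors (NAs dropped).
#' @param bin_edges Common bin edges for both curves.
#' @param labels Group labels.
#' @param xlab X-axis label.
#' @return A ggplot object.
#' @export
plot_cumulative_frequency <- function(group_a_values, group_b_values,
                                      bin_edges,
                                      labels = c("control", "disease"),
                                      xlab = "value") {
  df <- dplyr::bind_rows(
    dplyr::mutate(cumulative_frequency(group_a_values[!is.na(group_a_values)],
                                       bin_edges), group = labels[1]),
    dplyr::mutate(cumulative_frequency(group_b_values[!is.na(group_b_values)],
                                       bin_edges), group = labels[2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$edge, y = .data$cum_fraction,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = xlab, y = "cumulative frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a pairwise-correlation histogram
#'
#' @param hist_table Output of [correlation_histogram()].
#' @return A ggplot object.
#' @export
plot_correlation_histogram <- function(hist_table) {
  ggplot2::ggplot(hist_table,
                  ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = (hist_table$upper - hist_table$lower)[1] * 0.95) +
    ggplot2::labs(x = "pairwise correlation r", y = "gene pairs") +
    ggplot2::theme_minimal()
}

#' Plot a coexpression graph on a circular layout
#'
#' Genes on a circle, edges as chords — the circular network graph view
#' of a thresholded coexpression network. Layout is cosmetic only.
#'
#' @param graph A [build_graph()] result.
#' @param label_nodes Draw gene labels (sensible only for small graphs).
#' @return A ggplot object.
#' @export
plot_network_circle <- function(graph, label_nodes = FALSE) {
  stopifnot(inherits(graph, "correlation_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  th <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  nodes <- tibble(gene = igraph::V(g)$name, x = cos(th), y = sin(th))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  if (igraph::ecount(g) > 0) {
    e <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble(x = nodes$x[e[, 1]], y = nodes$y[e[, 1]],
                    xend = nodes$x[e[, 2]], yend = nodes$y[e[, 2]])
    p <- p + ggplot2::geom_segment(data = edges,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                xend = .data$xend,
                                                yend = .data$yend),
                                   colour = "grey50", linewidth = 0.2)
  }
  p <- p + ggplot2::geom_point(size = 1)
  if (label_nodes) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$gene),
                                size = 2, vjust = -1)
  }
  p
}
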