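# extract the genes x samples numeric matrix from a `values` tibble
# (gene column + one column per sample)
expression_matrix <- function(values, genes = NULL, samples = NULL) {
  stopifnot(is.data.frame(values), "gene" %in% names(values))
  if (anyDuplicated(values$gene)) abort("duplicate gene ids")
  m <- as.matrix(values[, setdiff(names(values), "gene"), drop = FALSE])
  rownames(m) <- values$gene
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(m))
    if (length(missing)) abort(sprintf("samples not in table: %s",
                                       paste(missing, collapse = ", ")))
    m <- m[, samples, drop = FALSE]
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) abort(sprintf("genes not in table: %s",
                                       paste(head(missing, 5), collapse = ", ")))
    m <- m[genes, , drop = FALSE]
  }
  m
}

#' Filter genes expressed in all samples
#'
#' Keeps genes whose expression exceeds `min_value` in every sample —
#' the "expressed in all samples" filter that removes near-threshold
#' genes before correlation analysis.
#'
#' @param values Expression tibble (`gene` column plus sample columns).
#' @param min_value Expression must be strictly greater than this in
#'   every sample (default 0).
#' @return Character vector of passing gene ids.
#' @export
filter_expressed <- function(values, min_value = 0) {
  assert_scalar_number(min_value, "min_value", 0)
  m <- expression_matrix(values)
  rownames(m)[apply(m > min_value, 1, all)]
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `|fold_change| >= fc_min` and `q_value <= q_max`
#' (both boundaries inclusive). Fold changes are on the signed
#' fold-change scale, so -2 means 2-fold down.
#'
#' @param de Data frame with columns `gene`, `fold_change`, `q_value`.
#' @param fc_min Minimum absolute fold change (default 1.5).
#' @param q_max Maximum q-value (default 0.05).
#' @return Character vector of passing gene ids.
#' @export
filter_de <- function(de, fc_min = 1.5, q_max = 0.05) {
  need <- c("gene", "fold_change", "q_value")
  if (!all(need %in% names(de))) {
    abort(sprintf("`de` must have columns %s", paste(need, collapse = ", ")))
  }
  if (fc_min < 1) abort("`fc_min` must be >= 1")
  if (q_max <= 0 || q_max >= 1) abort("`q_max` must be in (0, 1)")
  de$gene[abs(de$fold_change) >= fc_min & de$q_value <= q_max]
}

#' Pairwise gene-gene correlation across samples
#'
#' Pearson (default) or Spearman correlation for every unordered gene
#' pair across the chosen samples. Genes with zero variance across the
#' subset have no defined correlation; they are excluded and their count
#' reported in a message.
#'
#' @param values Expression tibble (`gene` column plus sample columns).
#' @param genes Optional subset of gene ids (default: all).
#' @param samples Optional subset of sample ids (default: all); at least
#'   3 are required.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_set`: list with `r` (symmetric
#'   matrix, unit diagonal), `genes`, `n_samples`, `method`, `excluded`.
#' @export
pairwise_correlation <- function(values, genes = NULL, samples = NULL,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- expression_matrix(values, genes = genes, samples = samples)
  if (ncol(m) < 3L) abort("need >= 3 samples for correlation")
  v <- apply(m, 1, sd)
  excluded <- rownames(m)[v == 0]
  if (length(excluded)) {
    inform(sprintf("excluding %d zero-variance gene(s) from correlation",
                   length(excluded)))
    m <- m[v > 0, , drop = FALSE]
  }
  r <- cor(t(m), method = method)
  diag(r) <- 1
  structure(list(r = r, genes = rownames(m), n_samples = ncol(m),
                 method = method, excluded = excluded),
            class = "correlation_set")
}

#' @export
print.correlation_set <- function(x, ...) {
  cat(sprintf("<correlation_set> %d genes x %d samples (%s)%s\n",
              length(x$genes), x$n_samples, x$method,
              if (length(x$excluded)) sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

#' @method tidy correlation_set
#' @export
tidy.correlation_set <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(gene_i = x$genes[idx[, 1]], gene_j = x$genes[idx[, 2]],
         r = x$r[idx])
}

#' Histogram of pairwise correlations
#'
#' Counts unordered gene-pair correlations in half-open bins
#' `[-1, -0.9), ..., [0.8, 0.9), [0.9, 1.0]`; the last bin is closed so
#' that r = 1 is counted.
#'
#' @param r_values Numeric vector of correlations in `[-1, 1]` (e.g. the
#'   `r` column of `tidy(correlation_set)`).
#' @param bin_width Bin width (default 0.1).
#' @return Tibble: `bin`, `lower`, `upper`, `count`.
#' @export
correlation_histogram <- function(r_values, bin_width = 0.1) {
  if (any(r_values < -1 - 1e-12 | r_values > 1 + 1e-12)) {
    abort("correlations must lie in [-1, 1]")
  }
  nb <- ceiling(2 / bin_width - 1e-9)
  lower <- -1 + (seq_len(nb) - 1) * bin_width
  upper <- pmin(lower + bin_width, 1)
  idx <- pmin(floor((pmin(pmax(r_values, -1), 1) + 1) / bin_width) + 1L, nb)
  tibble(bin = seq_len(nb), lower = lower, upper = upper,
         count = tabulate(idx, nbins = nb))
}

#' Build a signed, thresholded coexpression graph
#'
#' The positive graph links gene pairs with `r > threshold` ("correlation
#' greater than 0.9"); the negative graph links pairs with
#' `r < -threshold`. All genes remain as nodes, so isolated genes are
#' visible in connectivity metrics.
#'
#' @param correlations A [pairwise_correlation()] result.
#' @param threshold Correlation threshold in `(0, 1)` (default 0.9).
#' @param sign `"positive"` or `"negative"`.
#' @param inclusive If `TRUE`, use `>=` / `<=` at the threshold (the
#'   closed-interval convention used for histogram-based selection);
#'   default is strict, following the "greater than" phrasing.
#' @return An object of class `correlation_graph` wrapping an
#'   [igraph::graph] with edge attribute `r`, plus `threshold` and
#'   `sign`.
#' @export
build_graph <- function(correlations, threshold = 0.9,
                        sign = c("positive", "negative"),
                        inclusive = FALSE) {
  stopifnot(inherits(correlations, "correlation_set"))
  sign <- match.arg(sign)
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  r <- correlations$r
  ut <- upper.tri(r)
  keep <- if (sign == "positive") {
    if (inclusive) ut & r >= threshold else ut & r > threshold
  } else {
    if (inclusive) ut & r <= -threshold else ut & r < -threshold
  }
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(correlations$genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = correlations$genes)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    g <- igraph::set_edge_attr(g, "r", value = r[idx])
  }
  structure(list(graph = g, threshold = threshold, sign = sign),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph %s, |r| %s %.2f> %d nodes, %d edges\n",
              x$sign, ">", x$threshold,
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node degrees of a correlation graph
#'
#' @param graph A [build_graph()] result.
#' @return Tibble: `gene`, `degree`, sorted by decreasing degree then
#'   gene id.
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "correlation_graph"))
  d <- igraph::degree(graph$graph)
  out <- tibble(gene = names(d), degree = as.integer(d))
  out[order(-out$degree, out$gene), ]
}

#' Subgraph of the most connected genes
#'
#' Takes the `n` nodes of highest degree (ties at the cutoff broken by
#' gene id, deterministically) and all edges among them — the "top 200
#' most connected genes" selection for circular network graphs. If fewer
#' than `n` genes have any connection, all connected genes are taken and
#' the shortfall reported in a message.
#'
#' @param graph A [build_graph()] result.
#' @param n Number of genes to keep (default 200).
#' @return A `correlation_graph` restricted to the selected genes.
#' @export
top_connected_genes <- function(graph, n = 200) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (n < 1) abort("`n` must be >= 1")
  if (igraph::vcount(graph$graph) == 0L) abort("empty graph")
  deg <- graph_degrees(graph)
  connected <- deg[deg$degree > 0, ]
  if (nrow(connected) < n) {
    inform(sprintf("only %d gene(s) have degree > 0 (requested %d)",
                   nrow(connected), n))
    sel <- connected$gene
  } else {
    sel <- deg$gene[seq_len(n)]
  }
  out <- graph
  out$graph <- igraph::induced_subgraph(graph$graph, vids = sel)
  out
}

#' Connectivity and deconstruction metrics for two condition graphs
#'
#' Summarises each graph (edge count, connected-gene count, number of
#' connected components among connected genes, mean degree, largest
#' component size) and forms b/a ratios quantifying network
#' fragmentation — edge and component ratios near or below the planted
#' expectation indicate the network present in condition a has been
#' deconstructed in condition b.
#'
#' @param graph_a,graph_b Two [build_graph()] results (e.g. control vs
#'   perturbed condition) over the same gene universe.
#' @return List with `per_graph` (tibble, one row per graph) and
#'   `ratios` (named numeric vector of b/a ratios; `NaN` where a is 0).
#' @export
connectivity_metrics <- function(graph_a, graph_b) {
  stopifnot(inherits(graph_a, "correlation_graph"),
            inherits(graph_b, "correlation_graph"))
  one <- function(gr, label) {
    g <- gr$graph
    deg <- igraph::degree(g)
    gsub <- igraph::induced_subgraph(g, vids = which(deg > 0))
    comp <- if (igraph::vcount(gsub) > 0) igraph::components(gsub) else
      list(no = 0L, csize = integer(0))
    tibble(graph = label,
           n_edges = igraph::ecount(g),
           n_connected_genes = sum(deg > 0),
           n_components = comp$no,
           mean_degree = if (igraph::vcount(g)) mean(deg) else NA_real_,
           largest_component = if (length(comp$csize)) max(comp$csize) else 0L)
  }
  per <- dplyr::bind_rows(one(graph_a, "a"), one(graph_b, "b"))
  ratios <- c(
    edge_ratio = per$n_edges[2] / per$n_edges[1],
    connected_gene_ratio = per$n_connected_genes[2] / per$n_connected_genes[1],
    component_ratio = per$n_components[2] / per$n_components[1],
    mean_degree_ratio = per$mean_degree[2] / per$mean_degree[1],
    largest_component_ratio = per$largest_component[2] / per$largest_component[1]
  )
  list(per_graph = per, ratios = ratios)
}

#' Export a correlation graph
#'
#' `write_edge_list()` writes a TSV of `gene_i`, `gene_j`, `r`;
#' `write_graphml()` writes GraphML via igraph.
#'
#' @param graph A [build_graph()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "correlation_graph"))
  e <- igraph::as_edgelist(graph$graph)
  df <- data.frame(gene_i = e[, 1], gene_j = e[, 2],
                   r = igraph::edge_attr(graph$graph, "r") %||% numeric(0))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "correlation_graph"))
  igraph::write_graph(graph$graph, path, format = "graphml")
  invisible(path)
}
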