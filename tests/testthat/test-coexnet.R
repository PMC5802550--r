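make_expr <- function(m, genes = sprintf("g%02d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}

test_that("expression filters return exactly the planted gene sets", {
  set.seed(50)
  m <- matrix(runif(100 * 6, 1, 10), 100, 6)
  dropouts <- sample(100, 20)
  for (g in dropouts) m[g, sample(6, 1)] <- 0
  vals <- make_expr(m)
  passing <- filter_expressed(vals)
  expect_length(passing, 80)
  expect_setequal(passing, vals$gene[-dropouts])

  de <- tibble::tibble(gene = sprintf("d%04d", 1:1000),
                       fold_change = runif(1000, -1.4, 1.4),
                       q_value = runif(1000, 0.06, 1))
  chosen <- sample(1000, 37)
  de$fold_change[chosen] <- sample(c(-1, 1), 37, TRUE) * runif(37, 1.5, 4)
  de$q_value[chosen] <- runif(37, 0, 0.05)
  expect_setequal(filter_de(de), de$gene[chosen])

  # boundary conventions are inclusive
  edge <- tibble::tibble(gene = c("a", "b", "c"),
                         fold_change = c(1.5, -2, 1.49),
                         q_value = c(0.05, 0.01, 0.01))
  expect_setequal(filter_de(edge), c("a", "b"))
  expect_error(filter_de(edge[, 1:2]), "columns")
})

test_that("pairwise correlations match the naive textbook formula", {
  set.seed(51)
  m <- matrix(rlnorm(10 * 6), 10, 6)
  cs <- pairwise_correlation(make_expr(m))
  expect_equal(dim(cs$r), c(10, 10))
  expect_true(isSymmetric(cs$r))
  expect_equal(unname(diag(cs$r)), rep(1, 10))
  expect_true(all(abs(cs$r) <= 1 + 1e-12))
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(cs$r[i, j], oracle_pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }

  # perfect anticorrelation
  m2 <- rbind(1:6, 7 - (1:6))
  cs2 <- pairwise_correlation(make_expr(m2, c("up", "down")))
  expect_equal(cs2$r["up", "down"], -1)

  # zero-variance genes are excluded with a message
  m3 <- rbind(m, rep(5, 6))
  expect_message(cs3 <- pairwise_correlation(make_expr(m3)), "zero-variance")
  expect_equal(cs3$excluded, "g11")
  expect_error(pairwise_correlation(make_expr(m[, 1:2])), "3 samples")
})

test_that("correlation is invariant under positive affine gene transforms", {
  set.seed(52)
  m <- matrix(rnorm(8 * 10), 8, 10)
  base <- pairwise_correlation(make_expr(m))$r
  scaled <- m * runif(8, 0.5, 3) + runif(8, -2, 2)
  expect_equal(pairwise_correlation(make_expr(scaled))$r, base,
               tolerance = 1e-9)
})

test_that("correlation histogram endpoints follow the closed-last-bin rule", {
  h <- correlation_histogram(c(1, -1, 0.95, -0.95, 0))
  expect_equal(h$count[h$bin == 20], 2L)  # r = 1 and 0.95 in [0.9, 1.0]
  expect_equal(h$count[h$bin == 1], 2L)   # r = -1 and -0.95 in [-1, -0.9)
  expect_equal(sum(h$count), 5L)
  empty <- correlation_histogram(numeric(0))
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 20L)
  expect_error(correlation_histogram(1.5), "\\[-1, 1\\]")
})

test_that("thresholded graphs recover planted modules as components", {
  ex <- simulate_expression(seed = 60)
  samples <- ex$samples$sample_id[ex$samples$condition == "NCC"]
  cs <- pairwise_correlation(ex$values, samples = samples)
  g <- build_graph(cs, threshold = 0.9, sign = "positive")
  met <- connectivity_metrics(g, g)
  expect_equal(met$per_graph$n_components[1], 3L)
  expect_equal(met$ratios[["edge_ratio"]], 1)

  # module membership matches component membership for connected genes
  comp <- igraph::components(igraph::induced_subgraph(
    g$graph, vids = which(igraph::degree(g$graph) > 0)))
  members <- split(names(comp$membership), comp$membership)
  truth <- split(ex$truth$gene[!is.na(ex$truth$module)],
                 ex$truth$module[!is.na(ex$truth$module)])
  for (mod in truth) {
    hit <- vapply(members, function(mm) length(intersect(mm, mod)), integer(1))
    expect_gte(max(hit), 9)  # planted-partition recovery, size-10 modules
  }

  # within-module pairs overwhelmingly exceed the 0.9 threshold,
  # aggregated over 20 seeds
  fracs <- vapply(1:20, function(s) {
    exs <- simulate_expression(seed = 200 + s)
    ss <- exs$samples$sample_id[exs$samples$condition == "NCC"]
    tt <- tidy(pairwise_correlation(exs$values, samples = ss))
    mi <- exs$truth$module[match(tt$gene_i, exs$truth$gene)]
    mj <- exs$truth$module[match(tt$gene_j, exs$truth$gene)]
    w <- !is.na(mi) & !is.na(mj) & mi == mj
    mean(tt$r[w] > 0.9)
  }, numeric(1))
  expect_gte(mean(fracs), 0.9)
})

test_that("positive and negative graphs at one threshold share no pairs", {
  set.seed(53)
  m <- matrix(rnorm(20 * 6), 20, 6)
  cs <- pairwise_correlation(make_expr(m))
  gp <- build_graph(cs, threshold = 0.5, sign = "positive")
  gn <- build_graph(cs, threshold = 0.5, sign = "negative")
  ep <- apply(igraph::as_edgelist(gp$graph), 1, paste, collapse = "|")
  en <- apply(igraph::as_edgelist(gn$graph), 1, paste, collapse = "|")
  expect_length(intersect(ep, en), 0)
  expect_true(all(igraph::edge_attr(gp$graph, "r") > 0.5))
  expect_true(all(igraph::edge_attr(gn$graph, "r") < -0.5))
})

test_that("triangle graphs, degree ranking and shortfalls behave as stated", {
  r <- diag(3); r[upper.tri(r)] <- r[lower.tri(r)] <- 0.95
  cs <- structure(list(r = r, genes = c("a", "b", "c"), n_samples = 5,
                       method = "pearson", excluded = character(0)),
                  class = "correlation_set")
  g <- build_graph(cs)
  expect_equal(igraph::ecount(g$graph), 3)
  expect_equal(unname(igraph::degree(g$graph)), rep(2, 3))

  # all sub-threshold -> no edges
  low <- cs; low$r[upper.tri(low$r)] <- low$r[lower.tri(low$r)] <- 0.5
  expect_equal(igraph::ecount(build_graph(low)$graph), 0)

  # star graph: hub is the single most connected gene
  star <- igraph::make_star(10, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name", value = sprintf("g%02d", 1:10))
  sg <- structure(list(graph = star, threshold = 0.9, sign = "positive"),
                  class = "correlation_graph")
  expect_equal(igraph::V(top_connected_genes(sg, n = 1)$graph)$name, "g01")

  # shortfall: requesting 200 from a triangle returns all three with a message
  expect_message(t3 <- top_connected_genes(g, n = 200), "3 gene")
  expect_equal(igraph::vcount(t3$graph), 3)

  # top-n set equals a naive degree sort with id tie-breaks
  ex <- simulate_expression(seed = 61)
  ss <- ex$samples$sample_id[ex$samples$condition == "NCC"]
  cs2 <- pairwise_correlation(ex$values, samples = ss)
  g2 <- build_graph(cs2, threshold = 0.7)
  top <- top_connected_genes(g2, n = 15)
  deg <- igraph::degree(g2$graph)
  ref <- names(sort(deg, decreasing = TRUE))  # unstable for ties
  ord <- order(-deg, names(deg))
  expect_setequal(igraph::V(top$graph)$name, names(deg)[ord][1:15])
})

test_that("deconstruction metrics quantify edge loss between conditions", {
  tri <- igraph::make_full_graph(3)
  tri <- igraph::set_vertex_attr(tri, "name", value = c("a", "b", "c"))
  none <- igraph::make_empty_graph(3, directed = FALSE)
  none <- igraph::set_vertex_attr(none, "name", value = c("a", "b", "c"))
  ga <- structure(list(graph = tri, threshold = 0.9, sign = "positive"),
                  class = "correlation_graph")
  gb <- structure(list(graph = none, threshold = 0.9, sign = "positive"),
                  class = "correlation_graph")
  met <- connectivity_metrics(ga, gb)
  expect_equal(met$ratios[["edge_ratio"]], 0)
  expect_equal(met$per_graph$largest_component, c(3L, 0L))
})

test_that("expression tables and graphs round-trip through their file formats", {
  ex <- simulate_expression(n_genes = 12, n_modules = 1, module_size = 4,
                            n_samples_per_condition = 3, seed = 70)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ex, tf)
  back <- read_expression(tf)
  expect_equal(back$values, ex$values, tolerance = 1e-12)
  expect_equal(back$samples, ex$samples)

  cs <- pairwise_correlation(ex$values)
  g <- build_graph(cs, threshold = 0.5)
  ef <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, ef)
  el <- utils::read.delim(ef)
  expect_equal(nrow(el), igraph::ecount(g$graph))
  gf <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gf)
  g2 <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g$graph))
})
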