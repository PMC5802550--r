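#' Simulate replicate expression tables with planted correlated modules
#'
#' Generates a genes-by-samples expression table for two conditions.
#' In the correlated condition, genes belonging to the same planted module
#' share a latent factor: each module gene is
#' `sqrt(r) * factor + sqrt(1 - r) * noise`, giving an expected pairwise
#' Pearson correlation of `r = within_module_r` between module members.
#' In the decorrelated condition (when `decorrelate_condition = TRUE`) all
#' genes are independent, emulating a state in which coexpression networks
#' have not formed (or have been deconstructed). Non-module genes are
#' independent in both conditions. Latent z-scores are mapped onto a
#' non-negative expression scale by `expr = pmax(0, 100 + 10 * z)`, an
#' affine map that leaves Pearson correlations untouched (clipping at 10
#' standard deviations is never reached in practice).
#'
#' @param n_genes Total number of genes.
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module; `n_modules * module_size` must not
#'   exceed `n_genes`.
#' @param within_module_r Target within-module Pearson correlation, in
#'   `(0, 1)`.
#' @param n_samples_per_condition Samples (replicates) per condition;
#'   at least 3.
#' @param decorrelate_condition If `TRUE` (default) the second condition
#'   has no module structure; if `FALSE` both conditions share it.
#' @param seed Integer seed.
#' @param conditions Length-2 character vector of condition labels.
#' @return A list with elements `values` (tibble: `gene` column plus one
#'   column per sample), `samples` (tibble: `sample_id`, `condition`,
#'   `replicate`) and `truth` (tibble: `gene`, `module`; `NA` module for
#'   non-module genes).
#' @export
simulate_expression <- function(n_genes = 100,
                                n_modules = 3,
                                module_size = 10,
                                within_module_r = 0.95,
                                n_samples_per_condition = 30,
                                decorrelate_condition = TRUE,
                                seed = 1L,
                                conditions = c("NCC", "NPC")) {
  if (module_size * n_modules > n_genes) {
    abort("`module_size * n_modules` must not exceed `n_genes`")
  }
  if (within_module_r <= 0 || within_module_r >= 1) {
    abort("`within_module_r` must lie in (0, 1)")
  }
  if (n_samples_per_condition < 3) {
    abort("each condition needs at least 3 samples")
  }
  stopifnot(length(conditions) == 2L, !anyDuplicated(conditions))
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  module <- rep(NA_integer_, n_genes)
  module[seq_len(n_modules * module_size)] <-
    rep(seq_len(n_modules), each = module_size)

  ns <- n_samples_per_condition
  sample_tbl <- tibble(
    sample_id = c(sprintf("%s_r%02d", conditions[1], seq_len(ns)),
                  sprintf("%s_r%02d", conditions[2], seq_len(ns))),
    condition = rep(conditions, each = ns),
    replicate = rep(seq_len(ns), times = 2)
  )

  z <- with_local_seed(seed, {
    gen_cond <- function(correlated) {
      m <- matrix(rnorm(n_genes * ns), n_genes, ns)
      if (correlated) {
        f <- matrix(rnorm(n_modules * ns), n_modules, ns)
        idx <- which(!is.na(module))
        m[idx, ] <- sqrt(within_module_r) * f[module[idx], ] +
          sqrt(1 - within_module_r) * m[idx, ]
      }
      m
    }
    cbind(gen_cond(TRUE), gen_cond(!decorrelate_condition))
  })
  vals <- pmax(100 + 10 * z, 0)
  colnames(vals) <- sample_tbl$sample_id
  list(
    values = dplyr::bind_cols(tibble(gene = genes), as_tibble(vals)),
    samples = sample_tbl,
    truth = tibble(gene = genes, module = module)
  )
}
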