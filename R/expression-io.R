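#' Read and write replicate expression tables as TSV
#'
#' Genes in rows, one column per sample. Sample columns are named
#' `sampleid:condition:replicate`; `read_expression()` splits the header
#' back into a sample table so the pair round-trips.
#'
#' @param path TSV path.
#' @return `read_expression()`: a list with `values` (tibble: `gene`
#'   column plus one column per sample id) and `samples` (tibble:
#'   `sample_id`, `condition`, `replicate`), matching
#'   [simulate_expression()] output.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") abort("first column of an expression TSV must be 'gene'")
  hdr <- strsplit(names(df)[-1], ":", fixed = TRUE)
  bad <- lengths(hdr) != 3L
  if (any(bad)) {
    abort(sprintf("malformed sample header(s): %s",
                  paste(names(df)[-1][bad], collapse = ", ")))
  }
  samples <- tibble(
    sample_id = vapply(hdr, `[[`, "", 1),
    condition = vapply(hdr, `[[`, "", 2),
    replicate = as.integer(vapply(hdr, `[[`, "", 3))
  )
  names(df)[-1] <- samples$sample_id
  list(values = as_tibble(df), samples = samples)
}

#' @rdname read_expression
#' @param expr List with `values` and `samples` as returned by
#'   [simulate_expression()] or [read_expression()].
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.list(expr), all(c("values", "samples") %in% names(expr)))
  df <- as.data.frame(expr$values)
  s <- expr$samples
  m <- match(names(df)[-1], s$sample_id)
  if (anyNA(m)) abort("every value column must appear in `samples`")
  names(df)[-1] <- sprintf("%s:%s:%d", s$sample_id[m], s$condition[m], s$replicate[m])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `fold_change` (signed fold change) and
#' `q_value`, as consumed by [filter_de()].
#'
#' @param path TSV path.
#' @return A tibble with the three columns.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "fold_change", "q_value")
  if (!all(need %in% names(df))) {
    abort(sprintf("DE table must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(df$q_value < 0 | df$q_value > 1)) abort("q_value must lie in [0, 1]")
  as_tibble(df[, need])
}
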