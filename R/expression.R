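# Expression handling: isoform-to-gene pooling, log2 + per-sample z-score
# transformation, top-variable gene selection, and the 1-TPM expressed
# filter. All functions take wide tibbles (first column ids, one numeric
# column per sample) and return the same shape.

expr_matrix <- function(mat, arg = "mat") {
  if (!is.data.frame(mat) || ncol(mat) < 2L) {
    abort(sprintf("`%s` must be a data frame with an id column and sample columns", arg))
  }
  m <- as.matrix(mat[-1])
  if (!is.numeric(m)) abort(sprintf("`%s` sample columns must be numeric", arg))
  rownames(m) <- as.character(mat[[1]])
  m
}

rebuild_expr <- function(m, id_col_name) {
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble::tibble(!!id_col_name := rownames(m)), out)
  out
}

#' Pool isoform TPM to gene level
#'
#' Gene value = sum of its isoform TPM values per sample. Every isoform in
#' the matrix must be mapped; unmapped isoforms are an error that lists the
#' offending ids. Per-sample totals are conserved.
#'
#' @param isoform_tpm Wide tibble of isoform TPM (first column isoform ids).
#' @param gene_map Tibble with columns `isoform_id`, `gene_id`.
#' @return Wide tibble of gene TPM, genes in order of first appearance of
#'   each gene among the matrix isoforms.
#' @export
pool_to_gene <- function(isoform_tpm, gene_map) {
  m <- expr_matrix(isoform_tpm, "isoform_tpm")
  idx <- match(rownames(m), gene_map$isoform_id)
  if (anyNA(idx)) {
    abort(sprintf("unmapped isoform(s): %s",
                  paste(rownames(m)[is.na(idx)], collapse = ", ")))
  }
  gene <- gene_map$gene_id[idx]
  pooled <- rowsum(m, group = gene, reorder = FALSE)
  rebuild_expr(pooled, "gene_id")
}

#' Log2 + per-sample z-score transform
#'
#' `x -> log2(x + pseudocount)`, then each sample (column) is centred on its
#' mean and divided by its population (n-denominator) standard deviation.
#' A zero-variance column maps to all zeros.
#'
#' @param mat Wide TPM tibble (values >= 0).
#' @param pseudocount Added before the log (default 1).
#' @return Wide tibble of z-scores with the same ids.
#' @export
transform_expression <- function(mat, pseudocount = 1.0) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  m <- expr_matrix(mat)
  if (any(m < 0)) abort("TPM values must be >= 0")
  lg <- log2(m + pseudocount)
  z <- apply(lg, 2L, function(col) {
    s <- sqrt(mean((col - mean(col))^2))  # population sd
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  rownames(z) <- rownames(m)
  rebuild_expr(z, names(mat)[1])
}

#' Keep the most variable genes
#'
#' Ranks genes by row variance of the (transformed) values, descending;
#' ties are broken by gene id, lexicographic. If `top_n` exceeds the number
#' of genes, all are kept with a warning.
#'
#' @param mat Wide tibble (typically z-scores from [transform_expression()]).
#' @param top_n Number of genes to keep (default 2500).
#' @return The selected rows, most variable first.
#' @export
top_variable <- function(mat, top_n = 2500L) {
  if (top_n < 1L) abort("`top_n` must be >= 1")
  m <- expr_matrix(mat)
  if (top_n > nrow(m)) {
    warn(sprintf("`top_n` (%d) exceeds the number of genes (%d); keeping all",
                 top_n, nrow(m)))
    top_n <- nrow(m)
  }
  v <- apply(m, 1L, var)
  ord <- order(-v, rownames(m), method = "radix")
  mat[ord[seq_len(top_n)], , drop = FALSE]
}

#' Expressed-sequence test
#'
#' A sequence counts as expressed iff its maximum TPM across samples is at
#' or above `min_tpm` ("below 1 TPM" excludes; the boundary is kept).
#'
#' @param tpm_row_max Per-sequence maximum TPM across samples.
#' @param min_tpm Threshold (default 1).
#' @return Logical vector.
#' @export
is_expressed <- function(tpm_row_max, min_tpm = 1.0) {
  tpm_row_max >= min_tpm
}

#' Filter an expression matrix to expressed sequences
#'
#' @param mat Wide TPM tibble.
#' @inheritParams is_expressed
#' @return The rows whose maximum TPM is at least `min_tpm`.
#' @export
filter_expressed <- function(mat, min_tpm = 1.0) {
  m <- expr_matrix(mat)
  mat[is_expressed(apply(m, 1L, max), min_tpm), , drop = FALSE]
}
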