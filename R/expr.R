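#' Expression matrix container
#'
#' A light container for a log-scale gene-by-sample expression matrix together
#' with a per-sample batch (dataset-of-origin) label. Gene and sample
#' identifiers must be unique; rows containing missing values are dropped at
#' construction with a warning, so downstream code can assume a complete
#' matrix.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs), log-scale intensities.
#' @param batch per-sample batch labels (character or factor, length
#'   `ncol(values)`). Defaults to a single batch `"batch1"`.
#' @return an object of class `leat_expr` with elements `values` (matrix) and
#'   `batch` (factor named by sample ID).
#' @export
leat_expr <- function(values, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs gene IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (anyNA(values)) {
    keep <- !apply(values, 1L, anyNA)
    warning(sprintf("dropping %d gene row(s) with missing values",
                    sum(!keep)))
    values <- values[keep, , drop = FALSE]
  }
  if (is.null(batch)) batch <- rep("batch1", ncol(values))
  if (length(batch) != ncol(values))
    stop("`batch` must have one label per sample")
  batch <- factor(batch)
  names(batch) <- colnames(values)
  structure(list(values = values, batch = batch), class = "leat_expr")
}

#' @export
print.leat_expr <- function(x, ...) {
  cat(sprintf("<leat_expr> %d genes x %d samples, %d batch(es): %s\n",
              nrow(x$values), ncol(x$values), nlevels(x$batch),
              paste(levels(x$batch), collapse = ", ")))
  invisible(x)
}

#' @export
dim.leat_expr <- function(x) dim(x$values)

#' Subset an expression container
#'
#' `x[genes, samples]` subsets the matrix and keeps batch labels in step.
#'
#' @param x a [leat_expr] object.
#' @param i gene index (integer, logical, or gene IDs).
#' @param j sample index (integer, logical, or sample IDs).
#' @param ... ignored.
#' @export
`[.leat_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  leat_expr(x$values[i, j, drop = FALSE], batch = as.character(x$batch[j]))
}

as_expr_values <- function(x) {
  if (inherits(x, "leat_expr")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a `leat_expr` object or a numeric matrix")
}

#' Read / write expression TSV
#'
#' The on-disk format is tab-separated with the gene ID in the first column
#' (header `gene_id`) and one column per sample.
#'
#' @param path file path.
#' @param batch optional per-sample batch labels (recycled rules as in
#'   [leat_expr]); if `NULL` a single batch is assumed.
#' @return [leat_expr] for the reader; the writer returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, batch = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  leat_expr(m, batch = batch)
}

#' @param x a [leat_expr] object or numeric matrix to write.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  m <- as_expr_values(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
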