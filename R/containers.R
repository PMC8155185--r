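# coerce dense or sparse input to numeric dgCMatrix
as_sparse <- function(m) {
  if (is.matrix(m) ||
      (methods::is(m, "Matrix") && !methods::is(m, "CsparseMatrix")))
    m <- Matrix::Matrix(m * 1, sparse = TRUE)
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Gene-by-cell count matrix
#'
#' Light container for raw single-cell counts: a sparse non-negative
#' integer matrix (genes in rows, cells in columns) plus unique gene
#' symbols, unique cell barcodes, and an optional per-cell batch or
#' condition label.
#'
#' @param counts matrix or sparse Matrix of non-negative integers,
#'   genes x cells.
#' @param gene_ids character vector of unique gene symbols (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param batch optional per-cell label (recycled factor/character of
#'   length `ncol(counts)`).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts), batch = NULL) {
  counts <- as_sparse(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count matrix must have at least one gene and one cell")
  if (is.null(gene_ids) || is.null(barcodes))
    stop("gene_ids and barcodes are required")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(counts))
    stop(sprintf("gene table has %d entries but matrix has %d rows",
                 length(gene_ids), nrow(counts)))
  if (length(barcodes) != ncol(counts))
    stop(sprintf("barcode table has %d entries but matrix has %d columns",
                 length(barcodes), ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (anyDuplicated(barcodes)) stop("cell barcodes must be unique")
  if (length(counts@x) && (any(counts@x < 0) || any(counts@x != round(counts@x))))
    stop("counts must be non-negative integers")
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) == 1L) batch <- rep(batch, ncol(counts))
    if (length(batch) != ncol(counts))
      stop("batch must have one label per cell")
  }
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids,
                 barcodes = barcodes, batch = batch),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$batch))
    cat(sprintf(" (batches: %s)", paste(unique(x$batch), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Subset a CountMatrix by gene and/or cell index
#' @param x CountMatrix.
#' @param i gene index (logical, integer or character).
#' @param j cell index.
#' @param ... ignored.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  sub <- x$counts[i, j, drop = FALSE]
  count_matrix(sub, rownames(sub), colnames(sub),
               batch = if (!is.null(x$batch)) {
                 names(x$batch) <- x$barcodes
                 unname(x$batch[colnames(sub)])
               })
}

#' Normalized log-transformed expression matrix
#'
#' Holds log1p-transformed, library-size-normalized expression values
#' aligned to the CountMatrix it was derived from, plus the per-cell
#' size factors and optional cluster labels.
#'
#' @param values numeric matrix or sparse Matrix (genes x cells) of
#'   non-negative log1p expression values.
#' @param gene_ids,barcodes,batch as in [count_matrix()].
#' @param size_factors per-cell positive size factors.
#' @param clusters optional per-cell cluster labels.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              barcodes = colnames(values), batch = NULL,
                              size_factors = NULL, clusters = NULL) {
  values <- as_sparse(values)
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != nrow(values) || length(barcodes) != ncol(values))
    stop("id tables inconsistent with matrix dimensions")
  if (anyDuplicated(gene_ids) || anyDuplicated(barcodes))
    stop("gene ids and barcodes must be unique")
  if (length(values@x) && any(values@x < 0))
    stop("log1p expression values must be non-negative")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(values))
  if (length(size_factors) != ncol(values) || any(size_factors <= 0))
    stop("size_factors must be positive, one per cell")
  if (!is.null(clusters) && length(clusters) != ncol(values))
    stop("clusters must have one label per cell")
  dimnames(values) <- list(gene_ids, barcodes)
  structure(list(values = values, gene_ids = gene_ids, barcodes = barcodes,
                 batch = batch, size_factors = size_factors,
                 clusters = clusters),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  sub <- x$values[i, j, drop = FALSE]
  sel_cells <- structure(seq_along(x$barcodes), names = x$barcodes)[colnames(sub)]
  expression_matrix(sub, rownames(sub), colnames(sub),
                    batch = if (!is.null(x$batch)) x$batch[sel_cells],
                    size_factors = x$size_factors[sel_cells],
                    clusters = if (!is.null(x$clusters)) x$clusters[sel_cells])
}

#' Gene set collection
#'
#' Named list of gene-symbol vectors with a one-line description per
#' set, as parsed from a GMT file.
#'
#' @param sets named list of character vectors (no empty set, unique names).
#' @param description optional named character vector of descriptions.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop(sprintf("duplicate gene set name: %s",
                 names(sets)[duplicated(names(sets))][1]))
  if (any(lengths(sets) == 0L))
    stop(sprintf("empty gene set: %s", names(sets)[lengths(sets) == 0L][1]))
  sets <- lapply(sets, as.character)
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}
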