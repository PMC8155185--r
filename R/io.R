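#' Read a count matrix from disk
#'
#' Accepts either a CellRanger-style matrix-market directory
#' (`matrix.mtx` plus tab-separated `genes.tsv`/`features.tsv` and
#' `barcodes.tsv`, no header) or a dense CSV with gene ids in the first
#' column and barcodes in the header. The two/three-column genes.tsv
#' dialects are both accepted; the gene symbol is taken from the second
#' column when present, otherwise the first. A second column in
#' barcodes.tsv, when present, is read as the per-cell batch label.
#'
#' @param path directory containing the matrix-market triplet, a `.mtx`
#'   file (companion tables looked up next to it), or a dense `.csv`.
#' @param genes_as for dense CSV input, `"rows"` (default) or `"cols"`:
#'   the orientation of the gene axis in the file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, genes_as = c("rows", "cols")) {
  genes_as <- match.arg(genes_as)
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx in ", path)
    return(read_counts_mtx(mtx))
  }
  if (grepl("\\.mtx$", path)) return(read_counts_mtx(path))
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (genes_as == "cols") {
      m <- t(m)
      return(count_matrix(m, gene_ids = rownames(m), barcodes = ids))
    }
    return(count_matrix(m, gene_ids = ids, barcodes = colnames(m)))
  }
  stop("unrecognized count-matrix path: ", path)
}

read_counts_mtx <- function(mtx_path) {
  dirn <- dirname(mtx_path)
  gene_file <- file.path(dirn, c("genes.tsv", "features.tsv"))
  gene_file <- gene_file[file.exists(gene_file)][1]
  bc_file <- file.path(dirn, "barcodes.tsv")
  if (is.na(gene_file)) stop("no genes.tsv/features.tsv next to ", mtx_path)
  if (!file.exists(bc_file)) stop("no barcodes.tsv next to ", mtx_path)
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- utils::read.table(gene_file, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  bcs <- utils::read.table(bc_file, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (nrow(genes) != nrow(m))
    stop(sprintf("format error: %s has %d rows but %s has %d matrix rows",
                 basename(gene_file), nrow(genes), basename(mtx_path), nrow(m)))
  if (nrow(bcs) != ncol(m))
    stop(sprintf("format error: %s has %d rows but %s has %d matrix columns",
                 basename(bc_file), nrow(bcs), basename(mtx_path), ncol(m)))
  symbols <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  batch <- if (ncol(bcs) >= 2) bcs[[2]] else NULL
  count_matrix(m, gene_ids = symbols, barcodes = bcs[[1]], batch = batch)
}

#' Write a count matrix as a matrix-market triplet
#'
#' Writes `matrix.mtx`, `genes.tsv` (symbol duplicated into both of the
#' two CellRanger columns) and `barcodes.tsv` (batch label as second
#' column when present) into `dir`. Inverse of [read_counts()].
#'
#' @param cm a [count_matrix()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(cm$gene_ids, cm$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bc <- if (is.null(cm$batch)) data.frame(cm$barcodes)
        else data.frame(cm$barcodes, cm$batch)
  utils::write.table(bc, file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a GMT gene-set file
#'
#' Tab-separated, one set per line: set name, description, then gene
#' symbols. Blank lines are skipped; duplicate set names are an error.
#'
#' @param path path to the `.gmt` file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("format error in %s line %d: GMT lines need name, description and at least one gene",
                 basename(path), bad[1]))
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop(sprintf("duplicate gene set name in %s: %s", basename(path),
                 nm[duplicated(nm)][1]))
  sets <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])), nm)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a one-symbol-per-line gene list (e.g. transcription factors)
#' @param path text file, one gene symbol per line; blanks skipped.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Write a machine-readable run manifest
#'
#' Records the stage sequence, input/output shapes, seed and applied
#' thresholds of a pipeline run as JSON.
#'
#' @param manifest named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
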