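#' QC parameter bundle
#'
#' Defaults mirror the two workflow dialects: the day-20 workflow drops
#' genes found in fewer than 3 cells and cells more than 12 unscaled
#' median absolute deviations above the median mitochondrial fraction;
#' the day-32 workflow keeps cells with at least 1500 detected genes
#' and genes present in at least 10 cells.
#'
#' @param min_cells_per_gene presence threshold for genes.
#' @param min_genes_per_cell presence threshold for cells.
#' @param mito_mads MAD multiplier for the mitochondrial cut.
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param target_sum library-size target for normalization, a positive
#'   number or `"median"`.
#' @return list of class `QCParams`.
#' @export
qc_params <- function(min_cells_per_gene = 3, min_genes_per_cell = 1500,
                      mito_mads = 12, mito_prefix = "MT-",
                      target_sum = "median") {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0, mito_mads >= 0)
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 mito_mads = mito_mads, mito_prefix = mito_prefix,
                 target_sum = target_sum), class = "QCParams")
}

#' Drop genes detected in too few cells
#'
#' A gene is kept iff its count is nonzero in at least `min_cells`
#' cells (inclusive boundary); the cell set is unchanged.
#'
#' @param counts a [count_matrix()].
#' @param min_cells minimum number of cells with nonzero count.
#' @return Filtered [count_matrix()].
#' @export
filter_genes_min_cells <- function(counts, min_cells = 3) {
  stopifnot(inherits(counts, "CountMatrix"), min_cells >= 0)
  keep <- Matrix::rowSums(counts$counts > 0) >= min_cells
  if (!any(keep)) stop("no gene passes the presence filter")
  counts[keep, ]
}

#' Drop cells with too few detected genes
#'
#' A cell is kept iff it has nonzero counts for at least `min_genes`
#' genes (inclusive boundary).
#'
#' @param counts a [count_matrix()].
#' @param min_genes minimum number of detected genes per cell.
#' @return Filtered [count_matrix()].
#' @export
filter_cells_min_genes <- function(counts, min_genes = 1500) {
  stopifnot(inherits(counts, "CountMatrix"), min_genes >= 0)
  keep <- Matrix::colSums(counts$counts > 0) >= min_genes
  if (!any(keep)) stop("no cell passes the detected-genes filter")
  counts[, keep]
}

#' Per-cell mitochondrial count fraction
#' @param counts a [count_matrix()].
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @return named numeric vector (cells with zero total count get 0).
#' @export
mito_fraction <- function(counts, mito_prefix = "MT-") {
  mito <- startsWith(counts$gene_ids, mito_prefix)
  if (!any(mito))
    stop("no gene matches the mitochondrial prefix '", mito_prefix,
         "'; the filter would be vacuous")
  tot <- Matrix::colSums(counts$counts)
  frac <- ifelse(tot > 0,
                 Matrix::colSums(counts$counts[mito, , drop = FALSE]) /
                   pmax(tot, 1), 0)
  stats::setNames(frac, counts$barcodes)
}

#' Remove high-mitochondrial-content cells by a MAD rule
#'
#' Computes the per-cell mitochondrial count fraction and removes cells
#' strictly above `median + n_mads * MAD`, where the MAD is the
#' unscaled median absolute deviation (no 1.4826 consistency constant).
#' The removed barcodes are attached as attribute `removed_barcodes`.
#'
#' @param counts a [count_matrix()].
#' @param mito_prefix gene-symbol prefix marking mitochondrial genes.
#' @param n_mads MAD multiplier (default 12, deliberately lenient for
#'   cardiomyocytes, which are rich in mitochondria).
#' @return Filtered [count_matrix()] with attribute `removed_barcodes`.
#' @export
filter_cells_mito_mad <- function(counts, mito_prefix = "MT-", n_mads = 12) {
  stopifnot(inherits(counts, "CountMatrix"), n_mads >= 0)
  frac <- mito_fraction(counts, mito_prefix)
  med <- stats::median(frac)
  mad_u <- stats::median(abs(frac - med))
  cut <- med + n_mads * mad_u
  keep <- frac <= cut
  out <- counts[, keep]
  attr(out, "removed_barcodes") <- counts$barcodes[!keep]
  attr(out, "threshold") <- cut
  out
}

#' Library-size normalization followed by log1p
#'
#' Scales every cell so its total count equals `target_sum` (the median
#' library size when `target_sum = "median"`), then applies
#' `log(x + 1)`. All-zero cells are left at zero with a size factor of
#' 1 and a warning.
#'
#' @param counts a [count_matrix()].
#' @param target_sum positive number or `"median"`.
#' @return An [expression_matrix()] carrying the size factors.
#' @export
normalize_log1p <- function(counts, target_sum = "median") {
  stopifnot(inherits(counts, "CountMatrix"))
  tot <- Matrix::colSums(counts$counts)
  if (identical(target_sum, "median")) {
    target <- stats::median(tot[tot > 0])
  } else {
    stopifnot(is.numeric(target_sum), target_sum > 0)
    target <- target_sum
  }
  sf <- tot / target
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero cell(s): size factor set to 1")
    sf[tot == 0] <- 1
  }
  vals <- log1p(counts$counts %*% Matrix::Diagonal(x = 1 / sf))
  expression_matrix(vals, counts$gene_ids, counts$barcodes,
                    batch = counts$batch, size_factors = sf)
}

#' Apply a full QC dialect and normalize
#'
#' `day20`: gene presence filter then mitochondrial MAD cut. `day32`:
#' cell detected-genes filter then gene presence filter. Both end with
#' library-size normalization and log1p.
#'
#' @param counts a [count_matrix()].
#' @param dialect `"day32"` or `"day20"`.
#' @param params a [qc_params()].
#' @return list with `counts` (filtered [count_matrix()]), `expr`
#'   (an [expression_matrix()]) and `log` (before/after dimensions and
#'   removed barcodes).
#' @export
apply_qc <- function(counts, dialect = c("day32", "day20"),
                     params = qc_params()) {
  dialect <- match.arg(dialect)
  before <- dim(counts)
  removed <- character()
  if (dialect == "day20") {
    counts <- filter_genes_min_cells(counts, params$min_cells_per_gene)
    counts <- filter_cells_mito_mad(counts, params$mito_prefix,
                                    params$mito_mads)
    removed <- attr(counts, "removed_barcodes")
  } else {
    kept0 <- counts$barcodes
    counts <- filter_cells_min_genes(counts, params$min_genes_per_cell)
    removed <- setdiff(kept0, counts$barcodes)
    counts <- filter_genes_min_cells(counts, params$min_cells_per_gene)
  }
  pipeline_log("qc", "dialect %s: %d x %d -> %d x %d (removed %d cells)",
               dialect, before[1], before[2], nrow(counts$counts),
               ncol(counts$counts), length(removed))
  expr <- normalize_log1p(counts, params$target_sum)
  list(counts = counts, expr = expr,
       log = list(dialect = dialect, before = before, after = dim(counts),
                  removed_cells = removed))
}
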