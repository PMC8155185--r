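#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1 and mapped
#' back to the input order. `m` is the number of tests.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided over-representation test of a study gene list against
#' every set of a collection: with `N` background genes, `K` of them in
#' the set, and a study of size `n` overlapping the set in `k` genes,
#' `p = P[X >= k]` for `X ~ hypergeometric(N, K, n)`. Sets are
#' intersected with the background first; only sets with nonzero
#' background intersection are tested, and BH adjustment runs across
#' the tested sets. Rows are sorted by q then p.
#'
#' @param study_genes character vector of study genes (must be a
#'   subset of the background).
#' @param collection a [gene_set_collection()].
#' @param background_genes character vector defining the gene universe.
#' @return data.frame with columns `set_name`, `overlap`, `study_size`,
#'   `set_size_in_background`, `background_size`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(study_genes, collection, background_genes) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!length(study_genes)) stop("empty study gene list")
  if (!length(background_genes)) stop("empty background gene list")
  if (!all(study_genes %in% background_genes))
    stop("study genes must be a subset of the background")
  n <- length(study_genes)
  N <- length(background_genes)
  rows <- lapply(names(collection$sets), function(nm) {
    set_bg <- intersect(collection$sets[[nm]], background_genes)
    K <- length(set_bg)
    if (K == 0) return(NULL)
    k <- length(intersect(study_genes, set_bg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, study_size = n,
               set_size_in_background = K, background_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set intersects the background")
  out$q <- bh_adjust(out$p)
  out <- out[order(out$q, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell gene-set score with expression-matched controls
#'
#' Genes are binned into `n_bins` equal-count bins of average
#' expression across cells; for each set gene, `ctrl_per_gene` control
#' genes are sampled without replacement from its bin (set genes
#' excluded), and the per-cell score is the mean expression of the set
#' genes minus the mean expression of the pooled control genes.
#' Deterministic under `seed`.
#'
#' @param expr an [expression_matrix()].
#' @param gene_set character vector of set genes (intersected with the
#'   matrix; empty intersection is an error).
#' @param n_bins number of expression bins (default 25).
#' @param ctrl_per_gene controls sampled per set gene (default 50).
#' @param seed integer seed for the control sampling.
#' @param set_name label carried in the output.
#' @return data.frame (`barcode`, `set_name`, `score`).
#' @export
score_gene_set <- function(expr, gene_set, n_bins = 25, ctrl_per_gene = 50,
                           seed = 0L, set_name = "set") {
  stopifnot(inherits(expr, "ExpressionMatrix"), n_bins >= 1,
            ctrl_per_gene >= 1)
  genes <- expr$gene_ids
  set_genes <- intersect(gene_set, genes)
  if (!length(set_genes))
    stop("gene set does not intersect the expressed genes")
  avg <- Matrix::rowMeans(expr$values)
  # equal-count bins: equal-width cut on the rank
  bins <- as.integer(cut(rank(avg, ties.method = "first"),
                         breaks = n_bins, labels = FALSE))
  names(bins) <- genes
  set.seed(seed)
  ctrl <- unlist(lapply(set_genes, function(g) {
    pool <- genes[bins == bins[[g]]]
    pool <- setdiff(pool, set_genes)
    if (!length(pool)) return(character())
    pool[sample.int(length(pool), min(ctrl_per_gene, length(pool)))]
  }))
  ctrl <- unique(ctrl)
  if (!length(ctrl))
    stop("no control genes available outside the set")
  score <- Matrix::colMeans(expr$values[set_genes, , drop = FALSE]) -
    Matrix::colMeans(expr$values[ctrl, , drop = FALSE])
  data.frame(barcode = expr$barcodes, set_name = set_name,
             score = unname(score), row.names = NULL)
}
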