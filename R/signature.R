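#' Binarize an expression matrix
#'
#' Detection indicator: entries strictly greater than zero become 1,
#' everything else 0. Idempotent.
#'
#' @param expr an [expression_matrix()] or a plain (sparse) matrix.
#' @return sparse 0/1 matrix with the same dimnames.
#' @export
binarize <- function(expr) {
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  out <- as_sparse(as_sparse(m) > 0) * 1
  dimnames(out) <- dimnames(m)
  out
}

#' Thresholds of the binary enrichment search
#'
#' Boundary semantics follow the search definition: the target
#' prevalence bound is inclusive ("at least 50%"), the rest bound is
#' strict ("less than 25%"), the ratio bound is inclusive ("3 or
#' greater"; 2 for the transcription-factor list).
#'
#' @param min_target_prevalence minimum detection fraction in the
#'   target group.
#' @param max_rest_prevalence strict upper bound on the detection
#'   fraction in the remainder.
#' @param ratio_threshold minimum binary enrichment ratio.
#' @return list of class `SignatureParams`.
#' @export
signature_params <- function(min_target_prevalence = 0.50,
                             max_rest_prevalence = 0.25,
                             ratio_threshold = 3) {
  stopifnot(min_target_prevalence > 0, min_target_prevalence <= 1,
            max_rest_prevalence >= 0, max_rest_prevalence < 1,
            ratio_threshold > 0)
  structure(list(min_target_prevalence = min_target_prevalence,
                 max_rest_prevalence = max_rest_prevalence,
                 ratio_threshold = ratio_threshold),
            class = "SignatureParams")
}

#' Binary enrichment search for signature genes
#'
#' For every gene, the binarized expression is summed within the target
#' group and within the remainder and normalized by the group cell
#' counts, giving detection prevalences `p_target` and `p_rest`. The
#' binary enrichment ratio is `p_target / p_rest` (+Inf when
#' `p_rest = 0` and `p_target > 0`; defined as 0 when the gene is
#' absent everywhere). A gene passes iff
#' `p_target >= min_target_prevalence`, `p_rest < max_rest_prevalence`
#' and `ratio >= ratio_threshold`.
#'
#' Passing genes are sorted with infinite ratios first (by decreasing
#' `p_target`), then by decreasing finite ratio, ties broken by gene
#' symbol.
#'
#' @param expr an [expression_matrix()] (or 0/1 matrix).
#' @param group_labels per-cell labels defining the grouping (sample
#'   batches or cluster annotations both work).
#' @param target_group the label of the target group.
#' @param params a [signature_params()].
#' @return list of class `BinaryEnrichmentResult` with `table` (the
#'   full unfiltered per-gene data.frame: `gene`, `p_target`, `p_rest`,
#'   `ratio`, `passes_prevalence`, `passes_ratio`, `passes`) and
#'   `passing` (the sorted passing subset).
#' @export
binary_enrichment_search <- function(expr, group_labels, target_group,
                                     params = signature_params()) {
  b <- binarize(expr)
  group_labels <- as.character(group_labels)
  stopifnot(length(group_labels) == ncol(b))
  in_target <- group_labels == target_group
  if (!any(in_target))
    stop("target group '", target_group, "' absent from the labels")
  if (all(in_target))
    stop("remainder is empty: every cell is in the target group")
  p_t <- Matrix::rowSums(b[, in_target, drop = FALSE]) / sum(in_target)
  p_r <- Matrix::rowSums(b[, !in_target, drop = FALSE]) / sum(!in_target)
  ratio <- ifelse(p_t == 0 & p_r == 0, 0, p_t / p_r)  # 0/0 -> absent gene
  passes_prev <- p_t >= params$min_target_prevalence &
    p_r < params$max_rest_prevalence
  passes_ratio <- passes_prev & ratio >= params$ratio_threshold
  tab <- data.frame(gene = rownames(b), p_target = unname(p_t),
                    p_rest = unname(p_r), ratio = unname(ratio),
                    passes_prevalence = unname(passes_prev),
                    passes_ratio = unname(passes_ratio),
                    passes = unname(passes_ratio), row.names = NULL)
  pass <- tab[tab$passes, , drop = FALSE]
  inf <- is.infinite(pass$ratio)
  pass <- rbind(
    pass[inf, ][order(-pass$p_target[inf], pass$gene[inf]), ],
    pass[!inf, ][order(-pass$ratio[!inf], pass$gene[!inf]), ])
  structure(list(table = tab, passing = pass, params = params,
                 target_group = target_group),
            class = "BinaryEnrichmentResult")
}

#' @export
print.BinaryEnrichmentResult <- function(x, ...) {
  cat(sprintf("Binary enrichment search: target '%s', %d/%d genes pass\n",
              x$target_group, nrow(x$passing), nrow(x$table)))
  invisible(x)
}

#' Transcription-factor-restricted signature search
#'
#' The same binary enrichment statistic with the candidate universe
#' intersected with a known transcription-factor list before
#' thresholding, and a relaxed default ratio threshold of 2.
#'
#' @inheritParams binary_enrichment_search
#' @param tf_list character vector of transcription-factor symbols.
#' @return A `BinaryEnrichmentResult` over the TF universe.
#' @export
tf_signature <- function(expr, group_labels, target_group, tf_list,
                         params = signature_params(ratio_threshold = 2)) {
  keep <- expr$gene_ids %in% tf_list
  if (!any(keep)) {
    empty <- data.frame(gene = character(), p_target = numeric(),
                        p_rest = numeric(), ratio = numeric(),
                        passes_prevalence = logical(),
                        passes_ratio = logical(), passes = logical())
    return(structure(list(table = empty, passing = empty, params = params,
                          target_group = target_group),
                     class = "BinaryEnrichmentResult"))
  }
  binary_enrichment_search(expr[keep, ], group_labels, target_group, params)
}

#' Signal-to-noise gene ranking between two groups
#'
#' For each gene, the difference of group means divided by the sum of
#' the group sample standard deviations (n - 1 denominator), with a
#' small floor on the denominator as a purely numerical guard. Genes
#' are returned in decreasing SNR order (ties broken by gene symbol),
#' ready for preranked enrichment.
#'
#' @param expr an [expression_matrix()].
#' @param group_labels per-cell labels.
#' @param group_a,group_b the two labels to contrast (SNR > 0 means
#'   higher in `group_a`).
#' @param sd_floor denominator floor (default 1e-8; this is a guard
#'   against zero spread, not the 0.2-of-mean convention some
#'   enrichment tools apply).
#' @return data.frame of class `RankedGeneList` (`gene`, `snr`), sorted.
#' @export
snr_rank <- function(expr, group_labels, group_a, group_b,
                     sd_floor = 1e-8) {
  group_labels <- as.character(group_labels)
  stopifnot(length(group_labels) == ncol(expr$values))
  ia <- which(group_labels == group_a)
  ib <- which(group_labels == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 cells (standard deviation undefined)")
  ma <- as.matrix(expr$values[, ia, drop = FALSE])
  mb <- as.matrix(expr$values[, ib, drop = FALSE])
  snr <- (rowMeans(ma) - rowMeans(mb)) /
    pmax(apply(ma, 1, stats::sd) + apply(mb, 1, stats::sd), sd_floor)
  out <- data.frame(gene = expr$gene_ids, snr = unname(snr),
                    row.names = NULL)
  out <- out[order(-out$snr, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- c(a = group_a, b = group_b)
  attr(out, "sd_floor") <- sd_floor
  class(out) <- c("RankedGeneList", class(out))
  out
}

#' Prevalence heatmap matrix
#'
#' Mean binarized detection prevalence of the given genes in every
#' group — the genes-by-groups matrix behind the signature heatmaps.
#'
#' @param expr an [expression_matrix()].
#' @param group_labels per-cell labels.
#' @param genes genes to include (default: all).
#' @return numeric matrix genes x groups.
#' @export
prevalence_matrix <- function(expr, group_labels, genes = expr$gene_ids) {
  b <- binarize(expr)[genes, , drop = FALSE]
  group_labels <- as.character(group_labels)
  vapply(sort(unique(group_labels)), function(g)
    Matrix::rowSums(b[, group_labels == g, drop = FALSE]) /
      sum(group_labels == g),
    numeric(length(genes)))
}
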