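#' Scree-based choice of the number of principal components
#'
#' Scans the per-component standard deviations and keeps every
#' component up to the last appreciable drop: `chosen_n` is the largest
#' index `i` (scanning 2..n) for which
#' `(stdev[i-1] - stdev[i]) / stdev[1] >= tolerance` — the point after
#' which the standard deviations are similarly minimal. If no drop
#' qualifies, `floor_n` is returned.
#'
#' @param stdevs non-increasing per-component standard deviations
#'   (typically the first 30).
#' @param tolerance relative-drop threshold (fraction of `stdev[1]`).
#' @param floor_n fallback minimum (default 2).
#' @return list of class `PCSelection` with `stdevs`, `chosen_n`,
#'   `tolerance`.
#' @export
select_n_pcs <- function(stdevs, tolerance = 0.01, floor_n = 2) {
  stopifnot(length(stdevs) >= 1, tolerance >= 0)
  if (any(diff(stdevs) > 1e-8 * stdevs[1]))
    stop("component standard deviations must be non-increasing")
  chosen <- floor_n
  if (length(stdevs) >= 2) {
    drops <- (stdevs[-length(stdevs)] - stdevs[-1]) / stdevs[1]
    ok <- which(drops >= tolerance)
    if (length(ok)) chosen <- max(ok) + 1L
  }
  structure(list(stdevs = stdevs, chosen_n = as.integer(chosen),
                 tolerance = tolerance), class = "PCSelection")
}

#' Principal-component scores of an expression matrix
#'
#' Centered (unscaled) PCA of cells in gene space, optionally
#' restricted to the most over-dispersed genes (variance/mean ranking
#' of the de-logged values), as used for subset re-analysis.
#'
#' @param expr an [expression_matrix()].
#' @param n_pcs number of components to return.
#' @param n_hvg optional count of highly variable genes to restrict to.
#' @return list with `scores` (cells x PCs) and `sdev`.
#' @export
pca_scores <- function(expr, n_pcs = 17, n_hvg = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  vals <- expr$values
  if (!is.null(n_hvg) && n_hvg < nrow(vals)) {
    vals <- vals[highly_variable_genes(expr, n_hvg), , drop = FALSE]
  }
  x <- as.matrix(Matrix::t(vals))
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  list(scores = p$x, sdev = p$sdev)
}

#' Top over-dispersed genes
#' @param expr an [expression_matrix()].
#' @param n number of genes to keep.
#' @return character vector of gene ids, dispersion-ranked.
#' @export
highly_variable_genes <- function(expr, n = 2000) {
  de_logged <- expm1(expr$values)
  m <- Matrix::rowMeans(de_logged)
  v <- Matrix::rowMeans(de_logged^2) - m^2
  disp <- ifelse(m > 0, v / m, 0)
  expr$gene_ids[order(disp, decreasing = TRUE)[seq_len(min(n, length(m)))]]
}

# kNN graph in PC space with shared-nearest-neighbor Jaccard weights,
# pruned below `prune` (Seurat convention 1/15).
snn_graph <- function(scores, k = 10, prune = 1 / 15) {
  n <- nrow(scores)
  stopifnot(n >= k + 1)
  d <- as.matrix(stats::dist(scores))
  nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
  m <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  diag(m) <- 1  # a cell shares its own neighborhood
  sh <- methods::as(Matrix::tcrossprod(m), "TsparseMatrix")
  up <- sh@i < sh@j
  i <- sh@i[up] + 1L
  j <- sh@j[up] + 1L
  w <- sh@x[up] / (2 * (k + 1) - sh@x[up])  # Jaccard of the two kNN sets
  keep <- w >= prune
  igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
}

#' Leiden clustering at a fixed resolution
#'
#' Pipeline: centered PCA, k-nearest-neighbor graph (Euclidean in PC
#' space), shared-nearest-neighbor Jaccard edge weights, Leiden
#' community detection with the modularity objective. Deterministic
#' under a fixed seed. Cluster labels are "0", "1", ... in decreasing
#' cluster size.
#'
#' @param expr an [expression_matrix()].
#' @param n_pcs number of principal components.
#' @param n_neighbors k for the kNN graph.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed.
#' @param n_hvg optional highly-variable-gene restriction for the PCA.
#' @param graph optionally, a precomputed graph from an earlier call
#'   (skips PCA and graph construction).
#' @return factor of per-cell cluster labels, named by barcode.
#' @export
cluster_at_resolution <- function(expr, n_pcs = 17, n_neighbors = 10,
                                  resolution = 0.2, seed = 0L,
                                  n_hvg = NULL, graph = NULL) {
  if (is.null(graph)) {
    if (ncol(expr$values) < n_neighbors + 1)
      stop("need at least n_neighbors + 1 cells")
    graph <- snn_graph(pca_scores(expr, n_pcs, n_hvg)$scores,
                       k = n_neighbors)
  }
  set.seed(seed)
  part <- igraph::cluster_leiden(graph, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(part)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(as.character(seq_along(sizes) - 1L), names(sizes))
  factor(unname(relab[as.character(memb)]),
         levels = as.character(seq_along(sizes) - 1L)) |>
    stats::setNames(expr$barcodes)
}

# Tie-corrected rank-sum statistics for every row of a dense matrix.
# z is the normal-approximation statistic (no continuity correction,
# matching the z > 1.96 marker filter); the p-value uses the exact U
# distribution when the gene has no ties and both groups are small.
ranksum_rows <- function(mat, idx_a, idx_b, exact_max = 50) {
  na <- length(idx_a); nb <- length(idx_b); n <- na + nb
  stopifnot(na >= 1, nb >= 1)
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  res <- t(apply(sub, 1, function(x) {
    r <- rank(x)
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    s2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (s2 <= 0) return(c(z = 0, p = 1))
    z <- (u - na * nb / 2) / sqrt(s2)
    if (tie_term == 0 && na <= exact_max && nb <= exact_max) {
      p <- if (u <= na * nb / 2) 2 * stats::pwilcox(u, na, nb)
           else 2 * (1 - stats::pwilcox(u - 1, na, nb))
    } else {
      p <- 2 * stats::pnorm(-abs(z))
    }
    c(z = z, p = min(p, 1))
  }))
  list(z = res[, "z"], p = res[, "p"])
}

log_fold_change <- function(mat, idx_a, idx_b, pseudo = 1e-9) {
  ma <- rowMeans(expm1(mat[, idx_a, drop = FALSE]))
  mb <- rowMeans(expm1(mat[, idx_b, drop = FALSE]))
  log((ma + pseudo) / (mb + pseudo))
}

#' Count DE genes between neighboring clusters
#'
#' Each cluster's neighbor is the cluster whose expression centroid has
#' the highest Pearson correlation with its own. For every such pair,
#' differentially expressed genes are counted as genes with a two-sided
#' Wilcoxon rank-sum BH-adjusted q below `alpha` and an absolute
#' natural-log fold change (of de-logged means, pseudocount 1e-9) of at
#' least `min_abs_lfc`.
#'
#' @param expr an [expression_matrix()].
#' @param labels per-cell cluster labels.
#' @param alpha BH-adjusted significance level.
#' @param min_abs_lfc absolute log-fold-change floor.
#' @param neighbor_method `"nearest"` (centroid correlation) or
#'   `"all_pairs"`.
#' @return data.frame (`cluster_a`, `cluster_b`, `de_count`) with
#'   attribute `min_pair_de`; zero rows when fewer than two clusters.
#' @export
count_de_between_neighbors <- function(expr, labels, alpha = 0.05,
                                       min_abs_lfc = 1,
                                       neighbor_method = c("nearest",
                                                           "all_pairs")) {
  neighbor_method <- match.arg(neighbor_method)
  stopifnot(length(labels) == ncol(expr$values))
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  empty <- data.frame(cluster_a = character(), cluster_b = character(),
                      de_count = integer())
  if (length(cls) < 2) {
    attr(empty, "min_pair_de") <- NA_integer_
    return(empty)
  }
  mat <- as.matrix(expr$values)
  if (neighbor_method == "nearest") {
    cent <- vapply(cls, function(cl) rowMeans(mat[, labels == cl,
                                                  drop = FALSE]),
                   numeric(nrow(mat)))
    cc <- stats::cor(cent)
    diag(cc) <- -Inf
    pairs <- unique(t(apply(cbind(cls, cls[apply(cc, 1, which.max)]), 1,
                            sort)))
  } else {
    pairs <- t(utils::combn(cls, 2))
  }
  de <- apply(pairs, 1, function(pr) {
    if (pr[1] == pr[2]) stop("DE between a cluster and itself is undefined")
    ia <- which(labels == pr[1]); ib <- which(labels == pr[2])
    st <- ranksum_rows(mat, ia, ib)
    q <- bh_adjust(st$p)
    lfc <- log_fold_change(mat, ia, ib)
    sum(q < alpha & abs(lfc) >= min_abs_lfc)
  })
  out <- data.frame(cluster_a = pairs[, 1], cluster_b = pairs[, 2],
                    de_count = as.integer(de))
  attr(out, "min_pair_de") <- min(out$de_count)
  out
}

#' Cluster over a resolution grid and record the selection evidence
#'
#' Runs [cluster_at_resolution()] at each resolution (the PCA and
#' graph are built once) and counts DE genes between neighboring
#' clusters at each entry. A sweep entry with a single cluster gets
#' `min_pair_de = 0`: no neighbor pair can demonstrate separation, so
#' the entry is never selectable.
#'
#' @inheritParams cluster_at_resolution
#' @inheritParams count_de_between_neighbors
#' @param resolutions strictly increasing resolution grid.
#' @return data.frame of class `ClusterSweep` (`resolution`,
#'   `n_clusters`, `min_pair_de`) with the per-resolution label vectors
#'   in attribute `labels`.
#' @export
resolution_sweep <- function(expr, resolutions = seq(0.1, 2, by = 0.1),
                             n_pcs = 17, n_neighbors = 10, seed = 0L,
                             alpha = 0.05, min_abs_lfc = 1, n_hvg = NULL) {
  stopifnot(length(resolutions) >= 1, all(diff(resolutions) > 0))
  graph <- snn_graph(pca_scores(expr, n_pcs, n_hvg)$scores, k = n_neighbors)
  labs <- list()
  rows <- lapply(resolutions, function(res) {
    lab <- cluster_at_resolution(expr, resolution = res, seed = seed,
                                 graph = graph)
    labs[[as.character(res)]] <<- lab
    k <- length(unique(lab))
    minde <- if (k < 2) 0L else {
      de <- count_de_between_neighbors(expr, lab, alpha, min_abs_lfc)
      attr(de, "min_pair_de")
    }
    data.frame(resolution = res, n_clusters = k, min_pair_de = minde)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labs
  class(out) <- c("ClusterSweep", class(out))
  out
}

#' Select the clustering resolution from a sweep
#'
#' Among sweep entries whose minimum neighboring-pair DE count is
#' strictly positive, returns the resolution with the maximal number of
#' clusters; ties are broken by the lowest resolution. Errors when no
#' entry qualifies.
#'
#' @param sweep data.frame with columns `resolution`, `n_clusters`,
#'   `min_pair_de` (e.g. from [resolution_sweep()]).
#' @return the selected resolution (numeric scalar).
#' @export
select_resolution <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 1,
            all(c("resolution", "n_clusters", "min_pair_de") %in%
                  names(sweep)))
  ok <- sweep[!is.na(sweep$min_pair_de) & sweep$min_pair_de > 0, ]
  if (!nrow(ok))
    stop("no sweep entry keeps a positive DE count between neighboring clusters")
  ok <- ok[order(-ok$n_clusters, ok$resolution), ]
  ok$resolution[1]
}

#' One-vs-rest marker genes per cluster
#'
#' Two-sided Wilcoxon rank-sum test of each cluster against all other
#' cells, with tie-corrected normal-approximation z. Genes are retained
#' when z exceeds `z_min` (a positive z marks enrichment in the
#' cluster). q is BH-adjusted across genes within each cluster.
#'
#' @param expr an [expression_matrix()].
#' @param labels per-cell cluster labels.
#' @param z_min z threshold (default 1.96).
#' @return named list (one element per cluster) of data.frames with
#'   columns `gene`, `z`, `p`, `q`, `log_fold_change`, sorted by
#'   decreasing z.
#' @export
rank_genes_by_cluster <- function(expr, labels, z_min = 1.96) {
  stopifnot(length(labels) == ncol(expr$values))
  labels <- as.character(labels)
  mat <- as.matrix(expr$values)
  out <- lapply(sort(unique(labels)), function(cl) {
    ia <- which(labels == cl); ib <- which(labels != cl)
    st <- ranksum_rows(mat, ia, ib)
    df <- data.frame(gene = rownames(mat), z = st$z, p = st$p,
                     q = bh_adjust(st$p),
                     log_fold_change = log_fold_change(mat, ia, ib),
                     row.names = NULL)
    df <- df[df$z > z_min, , drop = FALSE]
    df[order(-df$z, df$gene), , drop = FALSE]
  })
  stats::setNames(out, sort(unique(labels)))
}
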