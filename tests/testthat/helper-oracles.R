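# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately share no code with the implementation.

# naive per-gene counting loop for the binary enrichment statistic
naive_binary_stats <- function(mat, labels, target, params) {
  in_t <- labels == target
  t(sapply(seq_len(nrow(mat)), function(g) {
    x <- mat[g, ]
    pt <- sum(x[in_t] > 0) / sum(in_t)
    pr <- sum(x[!in_t] > 0) / sum(!in_t)
    ratio <- if (pt == 0 && pr == 0) 0 else pt / pr
    prev_ok <- pt >= params$min_target_prevalence &&
      pr < params$max_rest_prevalence
    c(p_target = pt, p_rest = pr, ratio = ratio,
      passes = prev_ok && ratio >= params$ratio_threshold)
  }))
}

# exact two-sided rank-sum p by enumerating every assignment of the
# pooled observations to group A (tie-free data only)
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  # two-sided: double the smaller tail (U distribution is symmetric)
  if (u_obs <= mu) min(1, 2 * mean(u_all <= u_obs))
  else min(1, 2 * mean(u_all >= u_obs))
}

# hypergeometric upper-tail probability as an explicit combinatorial sum
oracle_hyper_p <- function(k, K, N, n) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  sum(sapply(k:jmax, function(j)
    choose(K, j) * choose(N - K, n - j))) / choose(N, n)
}

# plain data.frame -> ExpressionMatrix wrapper for small fixtures
expr_from_matrix <- function(m, batch = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  expression_matrix(m, batch = batch)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
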