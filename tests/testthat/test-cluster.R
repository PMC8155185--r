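test_that("scree selection keeps components up to the last appreciable drop", {
  sel <- select_n_pcs(c(10, 6, 3, 1, 0.95, 0.94), tolerance = 0.01)
  expect_equal(sel$chosen_n, 4L)
  # no elbow at all: fall back to the floor
  expect_equal(select_n_pcs(rep(2, 8))$chosen_n, 2L)
  # geometric decay ratio 0.5: drop_i = 0.5^(i-1); last >= 0.01 at i = 7
  s <- 10 * 0.5^(0:29)
  expect_equal(select_n_pcs(s, tolerance = 0.01)$chosen_n, 7L)
  expect_error(select_n_pcs(c(1, 2, 3)), "non-increasing")
})

test_that("Leiden labels are deterministic under seed and collapse a single blob", {
  cfg <- blob_sim_config(n_per_blob = 60, n_genes = 40, seed = 2)
  expr <- normalize_log1p(simulate_counts(cfg)$counts)
  a <- cluster_at_resolution(expr, n_pcs = 5, resolution = 0.5, seed = 9)
  b <- cluster_at_resolution(expr, n_pcs = 5, resolution = 0.5, seed = 9)
  expect_identical(a, b)
  # one homogeneous population at a tiny resolution -> a single cluster
  mu <- stats::setNames(rep(2, 30), sprintf("g%02d", 1:30))
  one <- sim_config(30, c(p = 120), list(population_spec("p", mu)),
                    mito_gene_fraction = 0, seed = 3)
  eone <- normalize_log1p(simulate_counts(one)$counts)
  lab <- cluster_at_resolution(eone, n_pcs = 5, resolution = 0.01, seed = 1)
  expect_equal(length(unique(lab)), 1L)
})

test_that("well-separated blobs are recovered at representative resolutions", {
  cfg <- blob_sim_config(seed = 4)
  sim <- simulate_counts(cfg)
  expr <- normalize_log1p(sim$counts)
  for (res in c(0.2, 0.6, 1.0)) {
    lab <- cluster_at_resolution(expr, n_pcs = 10, n_neighbors = 15,
                                 resolution = res, seed = 7)
    expect_gte(ari(lab, sim$truth$population), 0.95)
  }
})

test_that("rank-sum z and p match an exact enumeration oracle on tiny groups", {
  a <- c(5, 6, 7); b <- c(0, 1, 2)
  st <- matsig:::ranksum_rows(rbind(g = c(a, b)), 1:3, 4:6)
  # complete separation of 3 vs 3: U = 9, z = (9 - 4.5)/sqrt(9*7/12)
  expect_equal(unname(st$z), (9 - 4.5) / sqrt(9 * 7 / 12))
  expect_equal(unname(st$p), exact_ranksum_p(a, b))
  set.seed(8)
  for (i in 1:10) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    x <- sample(seq(0.1, 50, by = 0.1), na + nb)  # tie-free
    st <- matsig:::ranksum_rows(rbind(g = x), seq_len(na),
                                na + seq_len(nb))
    expect_equal(unname(st$p), exact_ranksum_p(x[seq_len(na)],
                                               x[na + seq_len(nb)]),
                 tolerance = 1e-12)
  }
})

test_that("constant genes are excluded and planted markers are found", {
  set.seed(5)
  m <- rbind(const = rep(3, 40),
             up = c(rnorm(20, 5, 0.3), rnorm(20, 0.2, 0.1)),
             noise = rnorm(40, 1, 0.2))
  m <- pmax(m, 0)
  colnames(m) <- sprintf("c%02d", 1:40)
  expr <- expr_from_matrix(m)
  lab <- rep(c("A", "B"), each = 20)
  rk <- rank_genes_by_cluster(expr, lab, z_min = 1.96)
  expect_true("up" %in% rk$A$gene)
  expect_false("const" %in% rk$A$gene)
  expect_false("up" %in% rk$B$gene)
})

test_that("DE counting between neighbors sees planted differences, not null noise", {
  set.seed(12)
  # two clusters from identical distributions: BH controls false positives
  n_null_high <- 0
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rpois(500 * 60, 1.5), 500, 60,
                dimnames = list(sprintf("g%03d", 1:500),
                                sprintf("c%02d", 1:60)))
    de <- count_de_between_neighbors(expr_from_matrix(log1p(m)),
                                     rep(c("A", "B"), each = 30))
    if (attr(de, "min_pair_de") > 10) n_null_high <- n_null_high + 1
  }
  expect_lte(n_null_high, 1)
  # 50 genes planted at 4-fold: nearly all detected
  set.seed(99)
  base <- matrix(rpois(500 * 80, 2), 500, 80)
  base[1:50, 41:80] <- rpois(50 * 40, 8)
  dimnames(base) <- list(sprintf("g%03d", 1:500), sprintf("c%02d", 1:80))
  de <- count_de_between_neighbors(expr_from_matrix(log1p(base)),
                                   rep(c("A", "B"), each = 40))
  expect_gte(de$de_count[1], 45)
  # a single cluster has no neighbor pairs
  de1 <- count_de_between_neighbors(expr_from_matrix(log1p(base)),
                                    rep("A", 80))
  expect_equal(nrow(de1), 0L)
})

test_that("resolution selection follows the max-clusters-with-positive-DE rule", {
  sweep <- data.frame(resolution = c(0.2, 0.4, 0.6, 0.8),
                      n_clusters = c(3, 5, 9, 10),
                      min_pair_de = c(50, 12, 4, 0))
  expect_equal(select_resolution(sweep), 0.6)
  expect_equal(select_resolution(data.frame(resolution = 0.3,
                                            n_clusters = 4,
                                            min_pair_de = 1)), 0.3)
  # tie on cluster count: the lower resolution wins
  tie <- data.frame(resolution = c(0.5, 0.7), n_clusters = c(6, 6),
                    min_pair_de = c(3, 2))
  expect_equal(select_resolution(tie), 0.5)
  expect_error(select_resolution(data.frame(resolution = 1, n_clusters = 2,
                                            min_pair_de = 0)), "positive")
  # property: never returns an entry with zero DE; order-invariant
  set.seed(21)
  for (i in 1:25) {
    sw <- data.frame(resolution = sort(runif(6, 0.1, 2)),
                     n_clusters = sample(2:12, 6, replace = TRUE),
                     min_pair_de = sample(0:5, 6, replace = TRUE))
    if (all(sw$min_pair_de == 0)) next
    res <- select_resolution(sw)
    expect_gt(sw$min_pair_de[sw$resolution == res], 0)
    expect_equal(select_resolution(sw[sample(6), ]), res)
  }
})

test_that("planted fibroblast ECM markers surface in that cluster's gene list", {
  cfg <- default_sim_config(seed = 3, cells_scale = 0.3)
  sim <- simulate_counts(cfg)
  expr <- normalize_log1p(sim$counts)
  lab <- cluster_at_resolution(expr, n_pcs = 17, resolution = 0.2, seed = 1)
  pop <- sim$truth$population[expr$barcodes]
  # cluster dominated by fibroblast-like cells
  fib_cluster <- names(which.max(
    vapply(levels(lab), function(l) mean(pop[lab == l] == "fibroblast"),
           numeric(1))))
  rk <- rank_genes_by_cluster(expr, lab)
  ecm <- sprintf("ECM%02d", 1:20)
  expect_gte(sum(ecm %in% rk[[fib_cluster]]$gene), 15)
})
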