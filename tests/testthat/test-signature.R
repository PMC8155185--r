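test_that("binarization is the detection indicator and is idempotent", {
  m <- matrix(c(0, 0.1, 3, 0, 0, 2), 2,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  b <- binarize(m)
  expect_equal(as.matrix(b),
               matrix(c(0, 1, 1, 0, 0, 1), 2,
                      dimnames = dimnames(m)))
  expect_equal(as.matrix(binarize(b)), as.matrix(b))
  expect_equal(sum(binarize(matrix(0, 3, 3,
    dimnames = list(letters[1:3], letters[4:6])))), 0)
})

worked_expr <- function() {
  # one gene: 6 of 8 target cells detected, 2 of 10 rest cells detected
  vals <- rbind(g1 = c(rep(1, 6), 0, 0, 1, 1, rep(0, 8)))
  colnames(vals) <- sprintf("c%02d", 1:18)
  expr_from_matrix(vals)
}

test_that("worked prevalence arithmetic: 0.75 vs 0.2 gives ratio 3.75", {
  labels <- rep(c("t", "r"), c(8, 10))
  res <- binary_enrichment_search(worked_expr(), labels, "t")
  expect_equal(res$table$p_target, 0.75)
  expect_equal(res$table$p_rest, 0.2)
  expect_equal(res$table$ratio, 3.75)
  expect_true(res$table$passes)
})

test_that("boundary semantics: rest prevalence exactly 0.25 fails", {
  # target 6/8 detected; rest 2/8 = 0.25 exactly
  vals <- rbind(g1 = c(rep(1, 6), 0, 0, 1, 1, rep(0, 6)))
  colnames(vals) <- sprintf("c%02d", 1:16)
  res <- binary_enrichment_search(expr_from_matrix(vals),
                                  rep(c("t", "r"), each = 8), "t")
  expect_false(res$table$passes)
  expect_false(res$table$passes_prevalence)
})

test_that("extreme and degenerate prevalences: infinite ratio and absent genes", {
  vals <- rbind(everywhere_t = c(rep(1, 5), rep(0, 5)),
                absent = rep(0, 10),
                both = rep(1, 10))
  colnames(vals) <- sprintf("c%02d", 1:10)
  labels <- rep(c("t", "r"), each = 5)
  res <- binary_enrichment_search(expr_from_matrix(vals), labels, "t")
  tab <- res$table
  expect_equal(tab$ratio[tab$gene == "everywhere_t"], Inf)
  expect_true(tab$passes[tab$gene == "everywhere_t"])
  expect_equal(tab$ratio[tab$gene == "absent"], 0)
  expect_false(tab$passes[tab$gene == "absent"])
  expect_false(tab$passes[tab$gene == "both"])
  expect_error(binary_enrichment_search(expr_from_matrix(vals), labels,
                                        "missing"), "absent")
})

test_that("a naive counting loop reproduces every statistic exactly", {
  params <- signature_params()
  set.seed(31)
  for (i in 1:30) {
    m <- matrix(rbinom(20 * 30, 1, runif(1, 0.1, 0.7)) * rexp(600), 20, 30,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%02d", 1:30)))
    labels <- sample(c("t", "r"), 30, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    res <- binary_enrichment_search(expr_from_matrix(m), labels, "t", params)
    orc <- naive_binary_stats(m, labels, "t", params)
    expect_equal(res$table$p_target, unname(orc[, "p_target"]))
    expect_equal(res$table$p_rest, unname(orc[, "p_rest"]))
    expect_equal(res$table$ratio, unname(orc[, "ratio"]))
    expect_identical(res$table$passes, unname(orc[, "passes"]) == 1)
  }
})

test_that("binary statistics are invariant to cell permutation and monotone rescaling", {
  set.seed(17)
  m <- matrix(rbinom(15 * 24, 1, 0.4) * rexp(360), 15, 24,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("c%02d", 1:24)))
  labels <- rep(c("t", "r"), each = 12)
  base <- binary_enrichment_search(expr_from_matrix(m), labels, "t")
  perm <- sample(24)
  shuf <- binary_enrichment_search(expr_from_matrix(m[, perm]),
                                   labels[perm], "t")
  expect_equal(base$table[order(base$table$gene), ],
               shuf$table[order(shuf$table$gene), ], ignore_attr = TRUE)
  scaled <- binary_enrichment_search(expr_from_matrix(sqrt(m) * 2.7),
                                     labels, "t")
  expect_equal(base$table, scaled$table)
  # stricter thresholds never admit a new gene
  for (p2 in list(signature_params(0.6, 0.25, 3),
                  signature_params(0.5, 0.15, 3),
                  signature_params(0.5, 0.25, 5))) {
    strict <- binary_enrichment_search(expr_from_matrix(m), labels, "t", p2)
    expect_true(all(strict$passing$gene %in% base$passing$gene))
  }
})

test_that("TF restriction intersects the universe and relaxes the ratio to 2", {
  # gene at prevalence 0.5 vs 0.2: ratio 2.5 passes TF list, not markers
  vals <- rbind(tfgene = c(rep(1, 5), rep(0, 5), rep(1, 4), rep(0, 16)),
                other = c(rep(1, 10), rep(0, 20)))
  colnames(vals) <- sprintf("c%02d", 1:30)
  labels <- rep(c("t", "r"), c(10, 20))
  expr <- expr_from_matrix(vals)
  marker <- binary_enrichment_search(expr, labels, "t")
  expect_false("tfgene" %in% marker$passing$gene)
  tf <- tf_signature(expr, labels, "t", tf_list = "tfgene")
  expect_identical(tf$passing$gene, "tfgene")
  # disjoint TF list: empty result
  none <- tf_signature(expr, labels, "t", tf_list = "nosuchgene")
  expect_equal(nrow(none$passing), 0L)
  # TF list covering all genes equals the plain search at threshold 2
  all_tf <- tf_signature(expr, labels, "t", tf_list = rownames(vals))
  plain2 <- binary_enrichment_search(expr, labels, "t",
                                     signature_params(ratio_threshold = 2))
  expect_equal(all_tf$table, plain2$table)
})

test_that("SNR ranking: worked value, antisymmetry, and degenerate groups", {
  vals <- rbind(g1 = c(1, 2, 3, 0, 0, 0), g2 = c(0, 1, 0, 1, 0, 1))
  colnames(vals) <- sprintf("c%d", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  expr <- expr_from_matrix(vals)
  r <- snr_rank(expr, labels, "A", "B")
  expect_equal(r$snr[r$gene == "g1"], 2)  # (2 - 0) / (1 + 0)
  swapped <- snr_rank(expr, labels, "B", "A")
  expect_equal(swapped$snr[match(r$gene, swapped$gene)], -r$snr)
  expect_identical(swapped$gene, rev(r$gene))
  # identical groups: all zero
  expect_equal(snr_rank(expr_from_matrix(
    rbind(g = c(1, 2, 1, 2), h = c(0, 3, 0, 3))),
    c("A", "A", "B", "B"), "A", "B")$snr, c(0, 0))
  expect_error(snr_rank(expr, c("A", "B", "B", "B", "B", "B"), "A", "B"),
               "2 cells")
})

test_that("planted maturation signature is recovered at default thresholds", {
  cfg <- default_sim_config(seed = 13)
  sim <- simulate_counts(cfg)
  expr <- normalize_log1p(sim$counts)
  res <- binary_enrichment_search(expr, sim$truth$population, "mature")
  planted <- c(cfg$planted_signature, cfg$planted_tf_signature)
  expect_gte(mean(cfg$planted_signature %in% res$passing$gene), 11 / 12)
  expect_true(all(res$passing$gene %in% planted))
  expect_equal(sum(grepl("^HK", res$passing$gene)), 0L)
})
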