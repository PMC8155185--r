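mk_trace <- function(baseline = c(95, 98, 100), oligo = c(42, 40, 41),
                     fccp = c(155, 160, 158), rot = c(10, 11, 9),
                     cell_count = 10000) {
  ocr_trace(time = seq_len(12) * 6.5,
            value = c(baseline, oligo, fccp, rot),
            phase = rep(c("baseline", "oligomycin", "fccp", "rot_aa"),
                        each = 3),
            cell_count = cell_count)
}

test_that("per-10k normalization scales values and requires a cell count", {
  tr <- mk_trace(cell_count = 20000)
  norm <- normalize_per_10k(tr)
  expect_equal(norm$data$value, tr$data$value / 2)
  id <- normalize_per_10k(mk_trace(cell_count = 10000))
  expect_equal(id$data$value, mk_trace()$data$value)
  expect_error(normalize_per_10k(mk_trace(cell_count = 0)), "positive")
})

test_that("mito-stress parameters follow the kit definitions exactly", {
  pm <- c(baseline = 100, oligomycin = 40, fccp = 160, rot_aa = 10)
  p <- mito_stress_params(simulate_ocr_trace(pm, noise_sd = 0))
  expect_equal(unlist(p[c("non_mito", "basal", "atp_linked", "proton_leak",
                          "maximal", "spare")]),
               c(non_mito = 10, basal = 90, atp_linked = 60,
                 proton_leak = 30, maximal = 150, spare = 60))
  # flat trace: everything zero except the non-mitochondrial floor
  flat <- mito_stress_params(simulate_ocr_trace(
    c(baseline = 7, oligomycin = 7, fccp = 7, rot_aa = 7), noise_sd = 0))
  expect_equal(unname(unlist(flat[2:6])), rep(0, 5))
  expect_equal(flat$non_mito, 7)
  # FCCP below baseline: negative spare capacity reported and flagged
  nospare <- mito_stress_params(simulate_ocr_trace(
    c(baseline = 100, oligomycin = 40, fccp = 80, rot_aa = 10),
    noise_sd = 0))
  expect_lt(nospare$spare, 0)
  expect_true(nospare$negative_spare)
  # a missing phase is named in the error
  bad <- ocr_trace(1:6, rep(5, 6), rep(c("baseline", "oligomycin"), each = 3))
  expect_error(mito_stress_params(bad), "fccp")
})

test_that("parameter identities hold to machine precision on noisy traces", {
  for (s in 1:25) {
    tr <- simulate_ocr_trace(c(baseline = 100, oligomycin = 40, fccp = 160,
                               rot_aa = 10), noise_sd = 8, seed = s)
    p <- mito_stress_params(tr)
    expect_identical(p$basal, p$atp_linked + p$proton_leak)
    expect_identical(p$spare, p$maximal - p$basal)
  }
})

test_that("normalization commutes with parameter extraction", {
  tr <- mk_trace(cell_count = 25000)
  a <- mito_stress_params(normalize_per_10k(tr))
  b <- mito_stress_params(tr)
  for (f in c("non_mito", "basal", "atp_linked", "proton_leak", "maximal",
              "spare"))
    expect_equal(a[[f]], b[[f]] * 10000 / 25000)
})

test_that("substrate and inhibitor contrasts are zero on identity, antisymmetric", {
  tr <- mk_trace()
  z <- fa_dependence(tr, tr)
  expect_equal(unname(unlist(z[1:6])), rep(0, 6))
  up <- mk_trace(fccp = c(205, 210, 208))
  d <- fa_dependence(up, tr)
  expect_equal(d$maximal, 50)
  expect_equal(d$fa_usage_indicator, 50)
  rev_d <- fa_dependence(tr, up)
  expect_equal(unlist(rev_d[1:6]), -unlist(d[1:6]))
  e <- eto_sensitivity(up, tr)
  expect_equal(unlist(e), unlist(d[1:6]))
})

test_that("glycolysis extraction follows the glucose/2-DG arithmetic", {
  tr <- ocr_trace(time = 1:9,
                  value = c(9, 10, 10, 30, 40, 35, 8, 8, 8),
                  phase = rep(c("baseline", "glucose", "twodg"), each = 3))
  g <- glycolysis_from_ecar(tr)
  expect_equal(g$glycolysis, 30)
  expect_equal(g$non_glycolytic, 8)
  flat <- ocr_trace(1:9, rep(4, 9),
                    rep(c("baseline", "glucose", "twodg"), each = 3))
  expect_equal(glycolysis_from_ecar(flat)$glycolysis, 0)
  partial <- ocr_trace(1:6, rep(4, 6),
                       rep(c("baseline", "glucose"), each = 3))
  expect_error(glycolysis_from_ecar(partial), "twodg")
})

test_that("the calibration polynomial matches its printed coefficients", {
  expect_equal(biowire_force(0, 5), 0)
  expect_equal(biowire_force(1, 1), 1.554716)
  expect_equal(biowire_force(10, 0), 15.756)
  # strictly increasing in x, increasing in y for x > 0
  x <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(biowire_force(x, 3)) > 0))
  expect_true(all(diff(biowire_force(3, x)) > 0))
  expect_error(biowire_force(-1, 1))
})

test_that("active force is the exact difference of total and passive force", {
  r <- active_force(force_record("T1", y = 1, passive_x = 0, total_x = 1))
  expect_equal(r$f_active, 1.554716)
  same <- active_force(force_record("T2", y = 2, passive_x = 3, total_x = 3))
  expect_equal(same$f_active, 0)
  set.seed(3)
  for (i in 1:20) {
    rec <- active_force(force_record("T", y = runif(1, 0, 5),
                                     passive_x = runif(1, 0, 2),
                                     total_x = runif(1, 0, 6)))
    expect_equal(rec$f_active + rec$f_passive, rec$f_total,
                 tolerance = 1e-12)
  }
})

test_that("flux and force CSV round trips preserve the records", {
  d <- withr::local_tempdir()
  traces <- list(A = mk_trace(), B = mk_trace(baseline = c(50, 51, 52)))
  traces$A$well <- "A"; traces$B$well <- "B"
  f <- file.path(d, "flux.csv")
  write_flux_csv(traces, f)
  back <- read_flux_csv(f)
  expect_equal(back$A$data$value, traces$A$data$value)
  expect_equal(back$B$data$phase, traces$B$data$phase)
  recs <- lapply(simulate_force_records(c(1, 2), c(1, 2), c(0.2, 0.5)),
                 active_force)
  ff <- file.path(d, "force.csv")
  write_force_csv(recs, ff)
  back2 <- read_force_csv(ff)
  expect_equal(back2[[1]]$f_active, recs[[1]]$f_active)
  expect_equal(back2[[2]]$f_total, recs[[2]]$f_total)
})

test_that("noisy traces still recover the planted parameters closely", {
  pm <- c(baseline = 100, oligomycin = 40, fccp = 160, rot_aa = 10)
  truth <- c(10, 90, 60, 30, 150, 60)
  ok <- sapply(1:20, function(s) {
    p <- mito_stress_params(simulate_ocr_trace(pm, noise_sd = 0.03 * 90,
                                               seed = s))
    est <- unlist(p[c("non_mito", "basal", "atp_linked", "proton_leak",
                      "maximal", "spare")])
    sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2)) <= 0.10
  })
  expect_gte(mean(ok), 0.95)
})
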