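# matsig

Maturation-signature discovery and functional-assay metrics for human
pluripotent stem cell (hPSC)-derived ventricular cardiomyocytes.

hPSC-derived cardiomyocytes are born metabolically immature: they burn
glucose, while the adult ventricular wall runs on fatty-acid oxidation
(FAO). A cardiomyocyte population driven toward maturity can be
recognized transcriptionally by a small set of genes whose expression
is nearly binary between immature and mature cells (e.g. *CD36*,
*ACSL1*-like FAO genes), and functionally by its respiration profile
and contraction force. `matsig` packages the complete analysis chain
for such a study, for computational biologists who want each stage as
a tested, reusable function:

* **Synthetic data with ground truth** — a negative-binomial
  single-cell count simulator with planted populations, on/off
  signature genes, mitochondrial-content outliers; extracellular-flux
  trace and contraction-force generators. Every downstream stage is
  validated against what was planted.
* **QC and normalization** — gene/cell presence filters with inclusive
  boundary semantics, a median-absolute-deviation mitochondrial cut,
  library-size normalization with `log1p`.
* **Clustering** — PCA with a scree rule for the component count,
  kNN/shared-nearest-neighbor graph, seeded Leiden clustering, and a
  resolution-selection rule: sweep resolutions and keep the most
  clusters such that every pair of neighboring clusters still has a
  positive count of differentially expressed genes.
* **The signature search** — binarize expression, compute detection
  prevalences in a target group vs the rest, and keep genes with
  prevalence ≥ 50% in the target, < 25% in the rest, and a binary
  enrichment ratio `p_target / p_rest` ≥ 3 (≥ 2 for the
  transcription-factor variant). Signal-to-noise gene ranking
  `(mean_A − mean_B)/(sd_A + sd_B)` for preranked enrichment.
* **Gene-set analytics** — per-cell scores against expression-matched
  control genes, hypergeometric over-representation with
  Benjamini–Hochberg control.
* **Assay calculators** — Mito-stress OCR parameters (basal,
  ATP-linked, proton leak, maximal, spare, non-mitochondrial),
  substrate/etomoxir contrasts, ECAR glycolysis, and the
  engineered-tissue force polynomial
  `f(x, y) = 1.55x + 0.00256x² + 0.002156xy` with active force =
  total − passive.

## Worked example

```r
library(matsig)

sim <- simulate_counts(default_sim_config(seed = 1))
sim$counts
#> CountMatrix: 800 genes x 2000 cells (batches: immature, mature)

qc <- apply_qc(sim$counts, dialect = "day32",
               qc_params(min_genes_per_cell = 150, min_cells_per_gene = 10))
#> [qc] dialect day32: 800 x 2000 -> 800 x 1997 (removed 3 cells)

lab <- cluster_at_resolution(qc$expr, n_pcs = 17, resolution = 0.2, seed = 1)
table(lab)
#>   0   1   2   3   4
#> 799 748 200 150 100

sig <- binary_enrichment_search(qc$expr,
                                sim$truth$population[qc$expr$barcodes],
                                "mature")
sig
#> Binary enrichment search: target 'mature', 12/800 genes pass
head(sig$passing[, c("gene", "p_target", "p_rest", "ratio")], 3)
#>        gene  p_target     p_rest    ratio
#> 26 MATSIG10 0.8936170 0.01585977 56.34490
#> 22 MATSIG06 0.8785982 0.01585977 55.39793
#> 18 MATSIG02 0.8961202 0.01669449 53.67760
```

The five clusters are the five simulated populations (mature,
immature, fibroblast-like, smooth-muscle-like, endoderm-like), and the
search recovers exactly the 12 planted signature genes: each is
detected in ~89% of mature cells and ~2% of the rest, a binary
enrichment ratio of ~50, far above the threshold of 3.

The assay calculators work on one well/tissue at a time:

```r
p <- mito_stress_params(simulate_ocr_trace(
  c(baseline = 100, oligomycin = 40, fccp = 160, rot_aa = 10),
  noise_sd = 0))
p
#> Mito-stress parameters: non-mito 10, basal 90, ATP-linked 60,
#>   proton leak 30, maximal 150, spare 60

active_force(force_record("T1", y = 1, passive_x = 0, total_x = 1))
#> ForceRecord T1: passive_x 0, total_x 1, y 1, active force 1.555
```

A full simulate → QC → cluster → signature → enrich run with a JSON
manifest is one call — `run_pipeline(toy_config(), out_dir = "run")` —
or, from a shell, `Rscript inst/scripts/matsig-cli.R run-all --out run`
(see `--help` for the per-stage subcommands).

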