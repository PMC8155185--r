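Package: matsig
Title: Maturation Signature Discovery and Functional Assay Metrics for
    Stem-Cell-Derived Cardiomyocytes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for deriving a metabolic maturation
    signature from single-cell RNA-seq of human pluripotent stem
    cell-derived ventricular cardiomyocytes, together with calculators
    for the functional assays used to validate maturation. Covers
    count-matrix QC (presence filters and a median-absolute-deviation
    mitochondrial cut), library-size normalization, PCA with scree-based
    component selection, shared-nearest-neighbor Leiden clustering with
    an explicit resolution-selection rule, one-vs-rest rank-sum marker
    statistics, a binary-enrichment (detection prevalence) signature
    search, signal-to-noise gene ranking, per-cell gene-set scoring,
    hypergeometric over-representation with Benjamini-Hochberg control,
    extracellular-flux (OCR/ECAR) parameter extraction, and an
    engineered-tissue contraction force model. A synthetic-data module
    generates count matrices, flux traces and force records with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
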