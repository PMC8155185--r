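#' Pipeline configuration
#'
#' Every tunable of every stage, with defaults matching the reference
#' day-32 workflow settings: QC keeps cells with >= 1500
#' detected genes and genes present in >= 10 cells, expression is
#' library-size normalized and log1p-transformed, clustering uses 17
#' PCs (or scree-based auto-selection over 30), 10 neighbors and Leiden
#' resolution 0.2, markers are filtered at |z| > 1.96, and the
#' signature search uses prevalence bounds 50%/25% with ratio
#' thresholds 3 (markers) and 2 (transcription factors).
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `qc = list(min_genes_per_cell = 150)`.
#' @return nested list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 0L,
    simulation = list(profile = "default", cells_scale = 1),
    qc = list(dialect = "day32", min_genes_per_cell = 1500,
              min_cells_per_gene = 10, mito_mads = 12, mito_prefix = "MT-",
              target_sum = "median"),
    cluster = list(n_pcs = 17, auto_pcs = FALSE, n_max_pcs = 30,
                   pc_tolerance = 0.01, n_neighbors = 10, resolution = 0.2,
                   sweep = FALSE, resolution_grid = seq(0.1, 2, by = 0.1),
                   alpha = 0.05, min_abs_lfc = 1, z_min = 1.96),
    signature = list(target = "mature", min_target_prevalence = 0.5,
                     max_rest_prevalence = 0.25, ratio_threshold = 3,
                     tf_ratio_threshold = 2, tf_list = NULL),
    enrichment = list(gmt = NULL, n_bins = 25, ctrl_per_gene = 50,
                      alpha = 0.05))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration (YAML)
#'
#' Values in the file override the package defaults; the round trip
#' through the file is lossless for every set field.
#'
#' @param path YAML path.
#' @return A `PipelineConfig`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `PipelineConfig`.
#' @return `path`, invisibly (for `write_config`).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Bundled toy configuration
#'
#' The default synthetic mixture scaled to 600 cells with QC thresholds
#' matched to the simulated sequencing depth, plus the bundled toy
#' gene-set collection and transcription-factor list. A full pipeline
#' run on this configuration takes seconds.
#'
#' @return A `PipelineConfig`.
#' @export
toy_config <- function() {
  cfg <- read_config(system.file("extdata", "toy_config.yaml",
                                 package = "matsig"))
  if (identical(cfg$enrichment$gmt, "bundled"))
    cfg$enrichment$gmt <- system.file("extdata", "toy_sets.gmt",
                                      package = "matsig")
  if (identical(cfg$signature$tf_list, "bundled"))
    cfg$signature$tf_list <- system.file("extdata", "toy_tfs.txt",
                                         package = "matsig")
  cfg
}

#' Run the full pipeline: simulate, QC, cluster, signature, enrich
#'
#' Executes every stage on synthetic data generated from the
#' configuration, writes the intermediate artifacts (counts directory,
#' cluster labels TSV, signature and enrichment CSVs) and a
#' machine-readable JSON run manifest into `out_dir`, and returns the
#' stage results.
#'
#' @param config a `PipelineConfig` (default [toy_config()]).
#' @param out_dir output directory.
#' @param seed optional override of `config$seed`.
#' @return list with `sim`, `qc`, `pc_selection`, `labels`, `sweep`,
#'   `signature`, `tf`, `enrichment`, `scores`, `manifest` (invisible).
#' @export
run_pipeline <- function(config = toy_config(), out_dir = tempfile("matsig"),
                         seed = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "matsig",
                   version = as.character(utils::packageVersion("matsig")),
                   seed = config$seed, stages = list())

  # simulate
  sim_cfg <- switch(config$simulation$profile,
    default = default_sim_config(seed = config$seed,
                                 cells_scale = config$simulation$cells_scale),
    blobs = blob_sim_config(seed = config$seed),
    stop("unknown simulation profile: ", config$simulation$profile))
  sim <- simulate_counts(sim_cfg)
  write_counts(sim$counts, file.path(out_dir, "counts"))
  pipeline_log("simulate", "%d genes x %d cells, seed %d",
               nrow(sim$counts$counts), ncol(sim$counts$counts), config$seed)
  manifest$stages$simulate <- list(shape = dim(sim$counts),
                                   profile = config$simulation$profile)

  # qc + normalize
  qp <- qc_params(min_cells_per_gene = config$qc$min_cells_per_gene,
                  min_genes_per_cell = config$qc$min_genes_per_cell,
                  mito_mads = config$qc$mito_mads,
                  mito_prefix = config$qc$mito_prefix,
                  target_sum = config$qc$target_sum)
  qc <- apply_qc(sim$counts, dialect = config$qc$dialect, params = qp)
  manifest$stages$qc <- c(qc$log[c("dialect", "before", "after")],
                          list(thresholds = qp[1:3],
                               n_removed_cells = length(qc$log$removed_cells),
                               removed_cells = qc$log$removed_cells))

  # cluster
  cc <- config$cluster
  pcsel <- NULL
  n_pcs <- cc$n_pcs
  if (isTRUE(cc$auto_pcs)) {
    sd30 <- pca_scores(qc$expr, n_pcs = cc$n_max_pcs)$sdev
    pcsel <- select_n_pcs(sd30[seq_len(min(cc$n_max_pcs, length(sd30)))],
                          tolerance = cc$pc_tolerance)
    n_pcs <- pcsel$chosen_n
    pipeline_log("cluster", "scree selection: %d PCs", n_pcs)
  }
  sweep <- NULL
  resolution <- cc$resolution
  if (isTRUE(cc$sweep)) {
    sweep <- resolution_sweep(qc$expr, resolutions = cc$resolution_grid,
                              n_pcs = n_pcs, n_neighbors = cc$n_neighbors,
                              seed = config$seed, alpha = cc$alpha,
                              min_abs_lfc = cc$min_abs_lfc)
    resolution <- select_resolution(sweep)
    pipeline_log("cluster", "sweep selected resolution %.2f", resolution)
  }
  labels <- cluster_at_resolution(qc$expr, n_pcs = n_pcs,
                                  n_neighbors = cc$n_neighbors,
                                  resolution = resolution,
                                  seed = config$seed)
  utils::write.table(data.frame(barcode = names(labels),
                                cluster = as.character(labels)),
                     file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pipeline_log("cluster", "resolution %.2f -> %d clusters", resolution,
               length(unique(labels)))
  manifest$stages$cluster <- list(n_pcs = n_pcs,
                                  n_neighbors = cc$n_neighbors,
                                  resolution = resolution,
                                  n_clusters = length(unique(labels)))

  # signature: target the mature sample batch
  sc <- config$signature
  group_labels <- qc$expr$batch
  sig <- binary_enrichment_search(
    qc$expr, group_labels, sc$target,
    signature_params(sc$min_target_prevalence, sc$max_rest_prevalence,
                     sc$ratio_threshold))
  utils::write.csv(sig$table, file.path(out_dir, "signature_table.csv"),
                   row.names = FALSE)
  utils::write.csv(sig$passing, file.path(out_dir, "signature_passing.csv"),
                   row.names = FALSE)
  pipeline_log("signature", "target '%s': %d genes pass", sc$target,
               nrow(sig$passing))
  tf <- NULL
  if (!is.null(sc$tf_list)) {
    tf <- tf_signature(qc$expr, group_labels, sc$target,
                       read_gene_list(sc$tf_list),
                       signature_params(sc$min_target_prevalence,
                                        sc$max_rest_prevalence,
                                        sc$tf_ratio_threshold))
    utils::write.csv(tf$passing, file.path(out_dir, "tf_passing.csv"),
                     row.names = FALSE)
  }
  manifest$stages$signature <- list(
    target = sc$target,
    thresholds = sc[c("min_target_prevalence", "max_rest_prevalence",
                      "ratio_threshold", "tf_ratio_threshold")],
    n_passing = nrow(sig$passing),
    n_tf_passing = if (is.null(tf)) NA else nrow(tf$passing))

  # enrichment: over-representation of the passing genes + per-cell scores
  enr <- NULL
  scores <- NULL
  if (!is.null(config$enrichment$gmt) && nrow(sig$passing) > 0) {
    coll <- read_gmt(config$enrichment$gmt)
    enr <- hypergeom_enrichment(sig$passing$gene, coll, qc$expr$gene_ids)
    utils::write.csv(enr, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE)
    scores <- do.call(rbind, lapply(names(coll$sets), function(nm) {
      s <- try(score_gene_set(qc$expr, coll$sets[[nm]],
                              n_bins = config$enrichment$n_bins,
                              ctrl_per_gene = config$enrichment$ctrl_per_gene,
                              seed = config$seed, set_name = nm),
               silent = TRUE)
      if (inherits(s, "try-error")) NULL else s
    }))
    utils::write.csv(scores, file.path(out_dir, "set_scores.csv"),
                     row.names = FALSE)
    pipeline_log("enrich", "%d sets tested, %d at q < %g", nrow(enr),
                 sum(enr$q < config$enrichment$alpha),
                 config$enrichment$alpha)
    manifest$stages$enrich <- list(n_sets = nrow(enr),
                                   alpha = config$enrichment$alpha,
                                   n_significant =
                                     sum(enr$q < config$enrichment$alpha))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, manifest_path)
  invisible(list(sim = sim, qc = qc, pc_selection = pcsel, labels = labels,
                 sweep = sweep, signature = sig, tf = tf, enrichment = enr,
                 scores = scores, manifest = manifest_path,
                 out_dir = out_dir))
}
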