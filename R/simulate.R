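#' Specification of one simulated cell population
#'
#' A population is defined by a per-gene negative-binomial mean profile
#' plus optional planted structure: near-binary "on/off" genes (an
#' expression gate with high detection prevalence in the owning
#' population and near-zero elsewhere), graded differential-expression
#' genes (fold changes folded into `mean_profile`), and substates
#' (small within-population subsets, e.g. stressed or proliferating
#' cells, carrying their own gated genes).
#'
#' @param name unique population label.
#' @param mean_profile named non-negative numeric vector, one mean per
#'   gene in the universe.
#' @param onoff optional data.frame with columns `gene`, `mu`,
#'   `prev_in`, `prev_out`: gated genes owned by this population. The
#'   realized detection prevalence is approximately
#'   `prev_in * P(NB(mu, dispersion) > 0)` inside the population and
#'   `prev_out * P(NB > 0)` elsewhere.
#' @param graded_de_genes named numeric vector of fold changes vs the
#'   reference profile (bookkeeping for ground truth; the folds must
#'   already be applied to `mean_profile`).
#' @param substates optional list of lists with fields `name`, `genes`,
#'   `mu`, `fraction`, and optionally `gate_in` (default 0.9) and
#'   `gate_out` (default 0.01).
#' @param batch batch/sample-of-origin label (defaults to `name`).
#' @return An object of class `PopulationSpec`.
#' @export
population_spec <- function(name, mean_profile, onoff = NULL,
                            graded_de_genes = NULL, substates = NULL,
                            batch = name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(names(mean_profile)) || any(mean_profile < 0))
    stop("mean_profile must be a named non-negative vector")
  if (!is.null(onoff)) {
    stopifnot(is.data.frame(onoff),
              all(c("gene", "mu", "prev_in", "prev_out") %in% names(onoff)))
    if (any(onoff$prev_in < 0 | onoff$prev_in > 1 |
            onoff$prev_out < 0 | onoff$prev_out > 1))
      stop("on/off gate prevalences must lie in [0, 1]")
    if (!all(onoff$gene %in% names(mean_profile)))
      stop("on/off genes must belong to the gene universe")
  }
  if (!is.null(graded_de_genes) &&
      !all(names(graded_de_genes) %in% names(mean_profile)))
    stop("graded DE genes must belong to the gene universe")
  structure(list(name = name, mean_profile = mean_profile, onoff = onoff,
                 graded_de_genes = graded_de_genes, substates = substates,
                 batch = batch),
            class = "PopulationSpec")
}

#' Simulation configuration
#'
#' Bundles the gene universe, the population mix and the count-model
#' parameters. Counts are drawn gene-wise negative-binomial with a
#' per-cell log-normal library-size factor; `nb_dispersion` is the NB
#' size parameter (`Inf` gives the Poisson limit). Mitochondrial genes
#' are, by convention, the genes whose symbol starts with `MT-`; the
#' first `ceiling(mito_gene_fraction * n_genes)` genes of the default
#' universe are named that way so the name-prefix QC filter is
#' exercised. `outlier_mito_cells` cells get their mitochondrial counts
#' multiplied by `outlier_mito_boost`, raising their mitochondrial
#' fraction at least three-fold over the typical cell.
#'
#' @param n_genes total number of genes.
#' @param cells_per_population named integer vector of cell counts.
#' @param populations list of [population_spec()] objects whose names
#'   match `names(cells_per_population)`.
#' @param nb_dispersion positive NB size parameter (`Inf` = Poisson).
#' @param library_size_mean,library_size_sd mean and log-scale sd of the
#'   per-cell log-normal size factor (sd 0 disables the variation).
#' @param mito_gene_fraction fraction of the gene universe carrying the
#'   `MT-` prefix (0 to 1).
#' @param outlier_mito_cells number of cells with inflated
#'   mitochondrial fraction.
#' @param outlier_mito_boost multiplier applied to the mitochondrial
#'   counts of the outlier cells.
#' @param planted_signature,planted_tf_signature gene sets recorded in
#'   the ground truth as the planted maturation signature and its
#'   transcription-factor counterpart.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `SimConfig`.
#' @export
sim_config <- function(n_genes, cells_per_population, populations,
                       nb_dispersion = 2, library_size_mean = 1,
                       library_size_sd = 0.3, mito_gene_fraction = 0.02,
                       outlier_mito_cells = 0, outlier_mito_boost = 10,
                       planted_signature = character(),
                       planted_tf_signature = character(), seed = 1L) {
  if (n_genes < 1L) stop("configuration error: need at least one gene")
  if (!length(cells_per_population) || any(cells_per_population < 1L) ||
      sum(cells_per_population) < 1L)
    stop("configuration error: need at least one cell")
  pop_names <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(pop_names)) stop("population names must be unique")
  if (!setequal(pop_names, names(cells_per_population)))
    stop("populations and cells_per_population must name the same groups")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (library_size_mean <= 0 || library_size_sd < 0)
    stop("library size parameters must be positive (sd non-negative)")
  if (mito_gene_fraction < 0 || mito_gene_fraction > 1)
    stop("mito_gene_fraction must lie in [0, 1]")
  if (outlier_mito_cells < 0) stop("outlier_mito_cells must be >= 0")
  for (p in populations) {
    if (length(p$mean_profile) != n_genes)
      stop(sprintf("population %s: mean_profile has %d genes, expected %d",
                   p$name, length(p$mean_profile), n_genes))
  }
  structure(list(n_genes = n_genes,
                 cells_per_population = cells_per_population,
                 populations = populations[match(names(cells_per_population),
                                                 pop_names)],
                 nb_dispersion = nb_dispersion,
                 library_size_mean = library_size_mean,
                 library_size_sd = library_size_sd,
                 mito_gene_fraction = mito_gene_fraction,
                 outlier_mito_cells = outlier_mito_cells,
                 outlier_mito_boost = outlier_mito_boost,
                 planted_signature = planted_signature,
                 planted_tf_signature = planted_tf_signature,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# Stage-specific substream seeds: adding a later stage never perturbs an
# earlier one. Stream order: 1 library sizes, 2 base counts, 3 on/off
# gates, 4 substates, 5 mito outliers.
substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a count matrix with known ground truth
#'
#' Draws gene-wise negative-binomial counts for every population in the
#' configuration, applies the on/off gates, substate gates and
#' mitochondrial-outlier boosts, and returns the matrix together with
#' the ground truth needed to audit downstream recovery. Deterministic
#' under a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (per-cell `population`, `state`, `batch`; per-population on/off and
#'   graded-gene bookkeeping; `planted_signature`,
#'   `planted_tf_signature`; `mito_outliers` barcodes; `size_factors`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  pops <- config$populations
  n_cells <- sum(config$cells_per_population)
  n_genes <- config$n_genes
  genes <- names(pops[[1]]$mean_profile)
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))
  pop_of_cell <- rep(names(config$cells_per_population),
                     config$cells_per_population)

  # stream 1: per-cell library-size factors
  set.seed(substream_seed(config$seed, 1))
  sf <- if (config$library_size_sd == 0) rep(config$library_size_mean, n_cells)
        else stats::rlnorm(n_cells,
                           meanlog = log(config$library_size_mean) -
                             config$library_size_sd^2 / 2,
                           sdlog = config$library_size_sd)

  # assemble the mean matrix: population profile, with on/off and
  # substate gene rows overridden by their gate-level mu everywhere
  mu <- matrix(0, n_genes, n_cells, dimnames = list(genes, barcodes))
  for (p in pops) mu[, pop_of_cell == p$name] <- p$mean_profile
  for (p in pops) {
    if (!is.null(p$onoff)) mu[p$onoff$gene, ] <- p$onoff$mu
    for (s in p$substates) mu[s$genes, ] <- s$mu
  }

  # stream 2: base counts
  set.seed(substream_seed(config$seed, 2))
  counts <- matrix(rnb(length(mu), mu = sweep(mu, 2, sf, `*`),
                       size = config$nb_dispersion),
                   n_genes, n_cells, dimnames = dimnames(mu))

  # stream 3: on/off gates
  set.seed(substream_seed(config$seed, 3))
  for (p in pops) {
    if (is.null(p$onoff)) next
    inside <- pop_of_cell == p$name
    for (k in seq_len(nrow(p$onoff))) {
      g <- p$onoff$gene[k]
      gate <- ifelse(inside,
                     stats::rbinom(n_cells, 1, p$onoff$prev_in[k]),
                     stats::rbinom(n_cells, 1, p$onoff$prev_out[k]))
      counts[g, ] <- counts[g, ] * gate
    }
  }

  # stream 4: substate assignment and gates
  set.seed(substream_seed(config$seed, 4))
  state_of_cell <- rep(NA_character_, n_cells)
  for (p in pops) {
    if (is.null(p$substates)) next
    inside <- which(pop_of_cell == p$name)
    state_of_cell[inside] <- "core"
    remaining <- inside
    for (s in p$substates) {
      take <- sample(remaining, round(s$fraction * length(inside)))
      state_of_cell[take] <- s$name
      remaining <- setdiff(remaining, take)
    }
    for (s in p$substates) {
      gate_in <- if (is.null(s$gate_in)) 0.9 else s$gate_in
      gate_out <- if (is.null(s$gate_out)) 0.01 else s$gate_out
      in_state <- state_of_cell == s$name & !is.na(state_of_cell) &
        pop_of_cell == p$name
      for (g in s$genes) {
        gate <- ifelse(in_state,
                       stats::rbinom(n_cells, 1, gate_in),
                       stats::rbinom(n_cells, 1, gate_out))
        counts[g, ] <- counts[g, ] * gate
      }
    }
  }

  # stream 5: mitochondrial outliers
  set.seed(substream_seed(config$seed, 5))
  mito_genes <- grep("^MT-", genes, value = TRUE)
  outliers <- character()
  if (config$outlier_mito_cells > 0 && length(mito_genes)) {
    pick <- sample(n_cells, config$outlier_mito_cells)
    counts[mito_genes, pick] <- counts[mito_genes, pick, drop = FALSE] *
      config$outlier_mito_boost
    outliers <- barcodes[sort(pick)]
  }

  batch_of_pop <- stats::setNames(vapply(pops, `[[`, "", "batch"),
                                  vapply(pops, `[[`, "", "name"))
  cm <- count_matrix(counts, gene_ids = genes, barcodes = barcodes,
                     batch = unname(batch_of_pop[pop_of_cell]))
  truth <- list(
    population = stats::setNames(pop_of_cell, barcodes),
    state = stats::setNames(state_of_cell, barcodes),
    batch = cm$batch,
    onoff = stats::setNames(lapply(pops, function(p)
      if (is.null(p$onoff)) character() else p$onoff$gene),
      vapply(pops, `[[`, "", "name")),
    graded = stats::setNames(lapply(pops, `[[`, "graded_de_genes"),
                             vapply(pops, `[[`, "", "name")),
    planted_signature = config$planted_signature,
    planted_tf_signature = config$planted_tf_signature,
    mito_outliers = outliers,
    size_factors = stats::setNames(sf, barcodes))
  list(counts = cm, truth = truth)
}

#' Default synthetic cardiomyocyte mixture
#'
#' The bundled study conditions: 2000 cells in five populations —
#' immature cardiomyocytes (750, their own batch), mature
#' cardiomyocytes (800), a smooth-muscle-like cardiomyocyte group
#' (150), contaminating fibroblast-like cells carrying ECM genes (200)
#' and an endoderm-like group (100). The mature population carries 12
#' planted near-binary signature genes (detection ~0.89 inside, ~0.02
#' elsewhere), 4 moderate-contrast transcription-factor genes (a
#' graded mean shift giving detection ~0.55 vs ~0.22, binary
#' enrichment ratio ~2.5), 40 genes
#' graded 3-fold up vs immature (and 20 graded up in immature), plus
#' small stressed and proliferating substates (12.5% of mature cells
#' each). 2% of genes are `MT-` prefixed, tuned to ~5% of counts, with
#' 5 mitochondrial-outlier cells boosted 10-fold.
#'
#' @param seed integer seed.
#' @param cells_scale optional multiplier applied to every population
#'   size (toy runs use < 1).
#' @return A [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, cells_scale = 1) {
  n_mito <- 16
  blocks <- list(
    mito = sprintf("MT-G%02d", seq_len(n_mito)),
    sig = sprintf("MATSIG%02d", 1:12),
    tf = sprintf("MATTF%d", 1:4),
    grdup = sprintf("GRDUP%02d", 1:40),
    grddn = sprintf("GRDDN%02d", 1:20),
    ecm = sprintf("ECM%02d", 1:20),
    endo = sprintf("ENDO%02d", 1:15),
    smc = sprintf("SMC%02d", 1:15),
    strs = sprintf("STRS%02d", 1:8),
    prol = sprintf("PROL%02d", 1:8))
  n_named <- sum(lengths(blocks))
  n_genes <- 800
  hk <- sprintf("HK%04d", seq_len(n_genes - n_named))
  genes <- c(unlist(blocks, use.names = FALSE), hk)

  base <- stats::setNames(numeric(n_genes), genes)
  # housekeeping means span a realistic detection range, deterministic
  base[hk] <- exp(seq(log(0.05), log(3), length.out = length(hk)))
  base[blocks$grdup] <- 1
  base[blocks$grddn] <- 1
  # moderate TF contrast as a graded mean shift: NB(mu, size 2) detection
  # ~0.22 at mu 0.265 and ~0.55 at mu 0.98 -> prevalence ratio ~2.5
  base[blocks$tf] <- 0.265

  profile_for <- function(adjust) {
    pr <- base
    pr <- adjust(pr)
    # mitochondrial share ~5% of expected counts
    pr[blocks$mito] <- 0.05 / 0.95 * sum(pr[setdiff(genes, blocks$mito)]) /
      n_mito
    pr
  }
  onoff_df <- function(g, mu, p_in, p_out)
    data.frame(gene = g, mu = mu, prev_in = p_in, prev_out = p_out)

  pops <- list(
    population_spec("immature",
      profile_for(function(p) { p[blocks$grddn] <- 3; p }),
      graded_de_genes = stats::setNames(rep(3, 20), blocks$grddn),
      batch = "immature"),
    population_spec("mature",
      profile_for(function(p) { p[blocks$grdup] <- 3; p[blocks$tf] <- 0.98; p }),
      onoff = onoff_df(blocks$sig, 8, 0.93, 0.02),
      graded_de_genes = stats::setNames(c(rep(3, 40), rep(3.7, 4)),
                                        c(blocks$grdup, blocks$tf)),
      substates = list(
        list(name = "stressed", genes = blocks$strs, mu = 4,
             fraction = 0.125),
        list(name = "proliferating", genes = blocks$prol, mu = 4,
             fraction = 0.125)),
      batch = "mature"),
    population_spec("smooth_muscle", profile_for(identity),
      onoff = onoff_df(blocks$smc, 6, 0.9, 0.02), batch = "mature"),
    population_spec("fibroblast", profile_for(identity),
      onoff = onoff_df(blocks$ecm, 6, 0.9, 0.02), batch = "mature"),
    population_spec("endoderm", profile_for(identity),
      onoff = onoff_df(blocks$endo, 6, 0.9, 0.02), batch = "mature"))

  cells <- round(c(immature = 750, mature = 800, smooth_muscle = 150,
                   fibroblast = 200, endoderm = 100) * cells_scale)
  sim_config(n_genes = n_genes, cells_per_population = cells,
             populations = pops, nb_dispersion = 2,
             library_size_mean = 1, library_size_sd = 0.3,
             mito_gene_fraction = n_mito / n_genes,
             outlier_mito_cells = 5, outlier_mito_boost = 10,
             planted_signature = blocks$sig,
             planted_tf_signature = blocks$tf, seed = seed)
}

#' Well-separated Gaussian-blob mixture for clustering checks
#'
#' Three equally sized populations, each with an exclusive block of
#' high-mean genes over a low common background — the planted labels
#' are trivially recoverable, so clustering behavior can be audited
#' across resolutions.
#'
#' @param n_per_blob cells per population.
#' @param n_genes universe size (split into three marker blocks plus
#'   background).
#' @param marker_mu mean of the exclusive marker genes.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
blob_sim_config <- function(n_per_blob = 200, n_genes = 120,
                            marker_mu = 5, seed = 1L) {
  n_mark <- floor(n_genes / 4)
  genes <- sprintf("G%03d", seq_len(n_genes))
  mk <- split(genes[seq_len(3 * n_mark)], rep(1:3, each = n_mark))
  base <- stats::setNames(rep(0.2, n_genes), genes)
  pops <- lapply(1:3, function(i) {
    pr <- base
    pr[mk[[i]]] <- marker_mu
    population_spec(paste0("blob", i), pr,
                    graded_de_genes = stats::setNames(rep(marker_mu / 0.2,
                                                          n_mark), mk[[i]]))
  })
  sim_config(n_genes = n_genes,
             cells_per_population = stats::setNames(rep(n_per_blob, 3),
                                                    paste0("blob", 1:3)),
             populations = pops, nb_dispersion = 2, library_size_mean = 1,
             library_size_sd = 0.2, mito_gene_fraction = 0,
             outlier_mito_cells = 0, seed = seed)
}

#' Simulate an extracellular-flux well trace
#'
#' One measurement per cycle with Gaussian noise around the supplied
#' phase means, phases in canonical injection order (mito-stress:
#' baseline, oligomycin, FCCP, rotenone/antimycin A; glycolysis:
#' baseline, glucose, 2-DG). The true phase means are recorded on the
#' returned trace.
#'
#' @param phase_means named numeric vector over one of the two
#'   canonical phase sets.
#' @param n_cycles_per_phase measurements per phase.
#' @param noise_sd Gaussian measurement noise (same flux units).
#' @param cell_count cells in the well (for per-10k normalization).
#' @param seed integer seed.
#' @param well,treatment labels carried on the trace.
#' @param cycle_minutes time between measurements.
#' @return An [ocr_trace()] with attribute `truth` = `phase_means`.
#' @export
simulate_ocr_trace <- function(phase_means, n_cycles_per_phase = 3,
                               noise_sd = 0, cell_count = 10000, seed = 1L,
                               well = "W1", treatment = NA_character_,
                               cycle_minutes = 6.5) {
  canon <- if (setequal(names(phase_means), mito_phases)) mito_phases
           else if (setequal(names(phase_means), glyco_phases)) glyco_phases
           else stop("phase_means must cover the mito-stress phases (",
                     paste(mito_phases, collapse = ", "),
                     ") or the glycolysis phases (",
                     paste(glyco_phases, collapse = ", "), ")")
  stopifnot(n_cycles_per_phase >= 1, noise_sd >= 0)
  set.seed(seed)
  phase <- rep(canon, each = n_cycles_per_phase)
  value <- phase_means[phase] + stats::rnorm(length(phase), 0, noise_sd)
  tr <- ocr_trace(time = seq_along(phase) * cycle_minutes,
                  value = unname(value), phase = phase, well = well,
                  treatment = treatment, cell_count = cell_count)
  attr(tr, "truth") <- phase_means[canon]
  tr
}

#' Simulate engineered-tissue force records
#'
#' Generates one record per tissue from true peak (contracting) and
#' passive (relaxed) rod deflections and tissue widths, with Gaussian
#' measurement noise on the deflections (truncated at zero). The true
#' active force implied by the calibration polynomial is recorded per
#' record.
#'
#' @param true_x true peak rod deflections under stimulation.
#' @param true_y tissue widths at the rod midspan.
#' @param passive_x true relaxed-state deflections.
#' @param noise_sd Gaussian noise on the measured deflections.
#' @param seed integer seed.
#' @return list of [force_record()] objects, each with attribute
#'   `truth_active`.
#' @export
simulate_force_records <- function(true_x, true_y, passive_x, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(length(true_x) == length(true_y),
            length(true_x) == length(passive_x), noise_sd >= 0)
  set.seed(seed)
  lapply(seq_along(true_x), function(i) {
    tx <- max(0, true_x[i] + stats::rnorm(1, 0, noise_sd))
    px <- max(0, passive_x[i] + stats::rnorm(1, 0, noise_sd))
    rec <- force_record(tissue = sprintf("T%02d", i), y = true_y[i],
                        passive_x = px, total_x = tx)
    attr(rec, "truth_active") <- biowire_force(true_x[i], true_y[i]) -
      biowire_force(passive_x[i], true_y[i])
    rec
  })
}
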