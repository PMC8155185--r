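mito_phases <- c("baseline", "oligomycin", "fccp", "rot_aa")
glyco_phases <- c("baseline", "glucose", "twodg")

#' Extracellular-flux well trace
#'
#' An ordered series of flux measurements (OCR in pmol O2/min, or ECAR)
#' for one well, each assigned to an injection phase. Phases must
#' appear contiguously in canonical injection order — mito-stress:
#' baseline, oligomycin (2 uM), FCCP (5 uM), rotenone/antimycin A
#' (0.5 uM each); glycolysis: baseline, glucose (10 mM), 2-DG
#' (100 mM) — with at least one measurement per present phase.
#'
#' @param time measurement times (minutes).
#' @param value flux values (finite).
#' @param phase per-measurement phase label.
#' @param well well id.
#' @param treatment treatment label (e.g. palmitate, BSA, ETO, vehicle).
#' @param cell_count cells counted in the well after the assay.
#' @return An object of class `OCRTrace`.
#' @export
ocr_trace <- function(time, value, phase, well = "W1",
                      treatment = NA_character_, cell_count = NA_real_) {
  stopifnot(length(time) == length(value), length(time) == length(phase))
  if (!all(is.finite(value))) stop("flux values must be finite")
  canon <- if (all(phase %in% mito_phases)) mito_phases
           else if (all(phase %in% glyco_phases)) glyco_phases
           else stop("unknown phase label(s): ",
                     paste(setdiff(phase, c(mito_phases, glyco_phases)),
                           collapse = ", "))
  runs <- rle(as.character(phase))$values
  present <- canon[canon %in% phase]
  if (!identical(runs, present))
    stop("phases must appear contiguously in canonical order (",
         paste(canon, collapse = " -> "), ")")
  o <- order(time)
  structure(list(data = data.frame(time = time[o], value = value[o],
                                   phase = phase[o]),
                 well = well, treatment = treatment,
                 cell_count = cell_count),
            class = "OCRTrace")
}

#' @export
print.OCRTrace <- function(x, ...) {
  cat(sprintf("OCRTrace well %s (%s): %d measurements, phases %s\n",
              x$well, x$treatment, nrow(x$data),
              paste(unique(x$data$phase), collapse = " -> ")))
  invisible(x)
}

phase_values <- function(trace, phase) {
  trace$data$value[trace$data$phase == phase]
}

#' Normalize a flux trace per 10,000 cells
#' @param trace an [ocr_trace()] with a positive `cell_count`.
#' @return the trace with every value multiplied by
#'   `10000 / cell_count`.
#' @export
normalize_per_10k <- function(trace) {
  stopifnot(inherits(trace, "OCRTrace"))
  if (is.na(trace$cell_count) || trace$cell_count <= 0)
    stop("cell_count must be positive to normalize per 10,000 cells")
  trace$data$value <- trace$data$value * 10000 / trace$cell_count
  attr(trace, "normalized") <- TRUE
  trace
}

#' Mito-stress respiration parameters from an OCR trace
#'
#' Assay-standard definitions: non-mitochondrial respiration is the
#' mean of the rotenone/antimycin A phase; basal respiration the last
#' baseline measurement minus non-mito; ATP-linked respiration the
#' last baseline minus the oligomycin-phase minimum; proton leak the
#' oligomycin minimum minus non-mito; maximal respiration the FCCP
#' maximum minus non-mito; spare capacity maximal minus basal. The
#' identities `basal = atp_linked + proton_leak` and
#' `spare = maximal - basal` hold exactly by construction. A negative
#' spare capacity (no spare energy capacity) is reported, not clamped,
#' and flagged.
#'
#' @param trace an [ocr_trace()] with all four mito-stress phases.
#' @param baseline_stat `"last"` (kit convention) or `"mean"`.
#' @param oligo_stat,fccp_stat,rot_aa_stat aggregation overrides
#'   (`"min"`, `"max"`, `"mean"`, `"last"`).
#' @return list of class `MitoStressParams`: `non_mito`, `basal`,
#'   `atp_linked`, `proton_leak`, `maximal`, `spare`,
#'   `negative_spare` flag.
#' @export
mito_stress_params <- function(trace, baseline_stat = "last",
                               oligo_stat = "min", fccp_stat = "max",
                               rot_aa_stat = "mean") {
  stopifnot(inherits(trace, "OCRTrace"))
  missing <- setdiff(mito_phases, unique(trace$data$phase))
  if (length(missing))
    stop("missing phase(s): ", paste(missing, collapse = ", "))
  agg <- function(x, stat) switch(stat, last = x[length(x)],
                                  mean = mean(x), min = min(x),
                                  max = max(x),
                                  stop("unknown aggregation: ", stat))
  base <- agg(phase_values(trace, "baseline"), baseline_stat)
  oligo <- agg(phase_values(trace, "oligomycin"), oligo_stat)
  fccp <- agg(phase_values(trace, "fccp"), fccp_stat)
  non_mito <- agg(phase_values(trace, "rot_aa"), rot_aa_stat)
  atp_linked <- base - oligo
  proton_leak <- oligo - non_mito
  basal <- atp_linked + proton_leak
  maximal <- fccp - non_mito
  spare <- maximal - basal
  structure(list(non_mito = non_mito, basal = basal,
                 atp_linked = atp_linked, proton_leak = proton_leak,
                 maximal = maximal, spare = spare,
                 negative_spare = spare < 0),
            class = "MitoStressParams")
}

#' @export
print.MitoStressParams <- function(x, ...) {
  cat(sprintf(paste0("Mito-stress parameters: non-mito %.3g, basal %.3g, ",
                     "ATP-linked %.3g, proton leak %.3g, maximal %.3g, ",
                     "spare %.3g%s\n"),
              x$non_mito, x$basal, x$atp_linked, x$proton_leak, x$maximal,
              x$spare, if (x$negative_spare) " (no spare capacity)" else ""))
  invisible(x)
}

mito_param_fields <- c("non_mito", "basal", "atp_linked", "proton_leak",
                       "maximal", "spare")

param_contrast <- function(trace_a, trace_b, ...) {
  pa <- mito_stress_params(trace_a, ...)
  pb <- mito_stress_params(trace_b, ...)
  d <- stats::setNames(unlist(pa[mito_param_fields]) -
                         unlist(pb[mito_param_fields]), mito_param_fields)
  as.list(d)
}

#' Exogenous fatty-acid dependence contrast
#'
#' Per-parameter difference of the mito-stress parameters between the
#' fatty-acid-substrate trace and the BSA control; the maximal-
#' respiration difference indicates exogenous fatty-acid usage.
#'
#' @param trace_substrate,trace_bsa normalized [ocr_trace()]s with the
#'   same phase structure.
#' @param ... aggregation overrides passed to [mito_stress_params()].
#' @return list of per-parameter differences (substrate minus BSA)
#'   plus `fa_usage_indicator` (the maximal difference).
#' @export
fa_dependence <- function(trace_substrate, trace_bsa, ...) {
  d <- param_contrast(trace_substrate, trace_bsa, ...)
  d$fa_usage_indicator <- d$maximal
  d
}

#' Etomoxir-sensitivity contrast
#'
#' Per-parameter difference vehicle minus etomoxir; a positive
#' difference quantifies the OCR component blocked by CPT1 inhibition,
#' i.e. dependent on fatty-acid oxidation.
#'
#' @param trace_vehicle,trace_eto normalized [ocr_trace()]s.
#' @param ... aggregation overrides passed to [mito_stress_params()].
#' @return list of per-parameter differences (vehicle minus ETO).
#' @export
eto_sensitivity <- function(trace_vehicle, trace_eto, ...) {
  param_contrast(trace_vehicle, trace_eto, ...)
}

#' Glycolysis from an ECAR trace
#'
#' Glycolysis is the glucose-phase maximum minus the last baseline
#' measurement; the non-glycolytic floor is the mean of the 2-DG phase.
#'
#' @param trace an [ocr_trace()] with phases baseline, glucose, twodg.
#' @return list with `glycolysis` and `non_glycolytic`.
#' @export
glycolysis_from_ecar <- function(trace) {
  stopifnot(inherits(trace, "OCRTrace"))
  missing <- setdiff(glyco_phases, unique(trace$data$phase))
  if (length(missing))
    stop("missing phase(s): ", paste(missing, collapse = ", "))
  base <- phase_values(trace, "baseline")
  list(glycolysis = max(phase_values(trace, "glucose")) -
         base[length(base)],
       non_glycolytic = mean(phase_values(trace, "twodg")))
}

#' Engineered-tissue force from rod deflection
#'
#' Calibration polynomial of the flexible-rod platform:
#' `f(x, y) = 1.55 x + 0.00256 x^2 + 0.002156 x y`, where `x` is the
#' rod deflection from its non-deflected origin and `y` the tissue
#' width at the rod midspan (calibration length units; the output is
#' labeled force units by convention of the calibration).
#'
#' @param x rod deflection(s), non-negative.
#' @param y tissue width(s), non-negative.
#' @return force value(s).
#' @export
biowire_force <- function(x, y) {
  stopifnot(all(x >= 0), all(y >= 0))
  1.55 * x + 0.00256 * x^2 + 0.002156 * x * y
}

#' One engineered tissue's force record
#'
#' @param tissue tissue id.
#' @param y tissue width at the rod midspan.
#' @param passive_x rod deflection in the relaxed state.
#' @param total_x peak rod deflection under electrical stimulation.
#' @return An object of class `ForceRecord` (forces unset until
#'   [active_force()]).
#' @export
force_record <- function(tissue, y, passive_x, total_x) {
  stopifnot(y >= 0, passive_x >= 0, total_x >= 0)
  structure(list(tissue = tissue, y = y, passive_x = passive_x,
                 total_x = total_x, f_passive = NA_real_,
                 f_total = NA_real_, f_active = NA_real_),
            class = "ForceRecord")
}

#' Fill the passive, total and active force of a record
#'
#' `f_passive` and `f_total` evaluate the calibration polynomial at
#' the relaxed and peak deflections; the active force is their
#' difference (total force during contraction minus the passive force
#' of the relaxed tissue).
#'
#' @param record a [force_record()].
#' @return the record with `f_passive`, `f_total`, `f_active` filled.
#' @export
active_force <- function(record) {
  stopifnot(inherits(record, "ForceRecord"))
  record$f_passive <- biowire_force(record$passive_x, record$y)
  record$f_total <- biowire_force(record$total_x, record$y)
  record$f_active <- record$f_total - record$f_passive
  record
}

#' @export
print.ForceRecord <- function(x, ...) {
  cat(sprintf("ForceRecord %s: passive_x %.3g, total_x %.3g, y %.3g",
              x$tissue, x$passive_x, x$total_x, x$y))
  if (!is.na(x$f_active)) cat(sprintf(", active force %.4g", x$f_active))
  cat("\n")
  invisible(x)
}

#' Read flux traces from long-format CSV
#'
#' Columns: `well`, `time`, `value`, `phase`, optional `treatment` and
#' `cell_count`. One [ocr_trace()] per well.
#'
#' @param path CSV path.
#' @return named list of [ocr_trace()] objects.
#' @export
read_flux_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time", "value", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("flux CSV ", basename(path), " lacks column(s): ",
         paste(miss, collapse = ", "))
  lapply(split(df, df$well), function(d)
    ocr_trace(d$time, d$value, d$phase, well = d$well[1],
              treatment = if ("treatment" %in% names(d)) d$treatment[1]
                          else NA_character_,
              cell_count = if ("cell_count" %in% names(d)) d$cell_count[1]
                           else NA_real_))
}

#' Write flux traces to long-format CSV
#' @param traces list of [ocr_trace()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(traces, path) {
  if (inherits(traces, "OCRTrace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(well = tr$well, time = tr$data$time, value = tr$data$value,
               phase = tr$data$phase, treatment = tr$treatment,
               cell_count = tr$cell_count)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read force measurements from CSV
#'
#' Columns: `tissue`, `deflection`, `width`, `state` (one `relaxed`
#' and one `contracting` row per tissue). Forces are filled via
#' [active_force()].
#'
#' @param path CSV path.
#' @return list of completed [force_record()] objects.
#' @export
read_force_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue", "deflection", "width", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("force CSV ", basename(path), " lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$state), c("relaxed", "contracting"))
  if (length(bad)) stop("unknown state value(s): ", paste(bad, collapse = ", "))
  lapply(split(df, df$tissue), function(d) {
    rel <- d[d$state == "relaxed", ]
    con <- d[d$state == "contracting", ]
    if (nrow(rel) != 1 || nrow(con) != 1)
      stop("tissue ", d$tissue[1],
           ": need exactly one relaxed and one contracting row")
    active_force(force_record(d$tissue[1], y = con$width,
                              passive_x = rel$deflection,
                              total_x = con$deflection))
  })
}

#' Write force records to CSV
#' @param records list of [force_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(records, path) {
  if (inherits(records, "ForceRecord")) records <- list(records)
  df <- do.call(rbind, lapply(records, function(r)
    rbind(data.frame(tissue = r$tissue, deflection = r$passive_x,
                     width = r$y, state = "relaxed"),
          data.frame(tissue = r$tissue, deflection = r$total_x,
                     width = r$y, state = "contracting"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Mean and standard error across technical-replicate wells
#' @param params_list list of `MitoStressParams`.
#' @return data.frame (`parameter`, `mean`, `sem`, `n`).
#' @export
summarize_mito_stress <- function(params_list) {
  stopifnot(length(params_list) >= 1)
  do.call(rbind, lapply(mito_param_fields, function(f) {
    x <- vapply(params_list, `[[`, numeric(1), f)
    data.frame(parameter = f, mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               n = length(x))
  }))
}
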