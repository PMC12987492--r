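#' Run configuration
#'
#' Bundles everything one prediction run needs: the file layout, the
#' parameter set, the annotation, optional genome, output directory and
#' output switches. A configuration can be written to and re-read from a
#' YAML file ([write_run_config()] / [read_run_config()]) for reproducible
#' re-runs; the round trip is exact.
#'
#' @param layout An [experiment_layout] (or the files data.frame for one).
#' @param annotation Path to the GFF3 annotation.
#' @param params A [tss_params].
#' @param genome Optional path to a genome FASTA (enables the upstream
#'   sequence column of the MasterTable).
#' @param output_dir Output directory.
#' @param percentile_rank Percentile rank of the normalization (default 0.9).
#' @param normalize_percentile,normalize_enrichment Stage switches of the
#'   inter-library normalization.
#' @param export_normalized Also write the normalized tracks as wiggle.
#' @param write_gff Write one TSS GFF3 per condition.
#' @return An object of class `run_config`.
#' @export
run_config <- function(layout, annotation, params = tss_params(),
                       genome = NULL, output_dir = "tsscall_out",
                       percentile_rank = 0.9,
                       normalize_percentile = TRUE,
                       normalize_enrichment = TRUE,
                       export_normalized = FALSE, write_gff = TRUE) {
  if (!inherits(layout, "experiment_layout"))
    layout <- experiment_layout(layout)
  stopifnot(inherits(params, "tss_params"))
  structure(list(layout = layout, annotation = annotation, params = params,
                 genome = genome, output_dir = output_dir,
                 percentile_rank = percentile_rank,
                 normalize_percentile = normalize_percentile,
                 normalize_enrichment = normalize_enrichment,
                 export_normalized = export_normalized,
                 write_gff = write_gff),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(
    conditions = config$layout$conditions,
    files = lapply(seq_len(nrow(config$layout$files)), function(i)
      as.list(config$layout$files[i, ])),
    annotation = config$annotation,
    genome = config$genome,
    output_dir = config$output_dir,
    percentile_rank = config$percentile_rank,
    normalize_percentile = config$normalize_percentile,
    normalize_enrichment = config$normalize_enrichment,
    export_normalized = config$export_normalized,
    write_gff = config$write_gff,
    parameters = unclass(config$params))
  obj$parameters$preset <- config$params$preset  # NULL drops the key
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  files <- do.call(rbind, lapply(obj$files, as.data.frame))
  pars <- obj$parameters
  params <- tss_params(
    step_height = pars$step_height, step_factor = pars$step_factor,
    enrichment_factor = pars$enrichment_factor,
    step_height_reduction = pars$step_height_reduction,
    step_factor_reduction = pars$step_factor_reduction,
    window = pars$window, reduction_mode = pars$reduction_mode,
    cross_replicate_shift = pars$cross_replicate_shift,
    cross_condition_shift = pars$cross_condition_shift,
    min_replicates = pars$min_replicates, utr_length = pars$utr_length,
    antisense_distance = pars$antisense_distance,
    primary_rule = pars$primary_rule)
  params$preset <- pars$preset
  run_config(experiment_layout(files, conditions = obj$conditions),
             annotation = obj$annotation, params = params,
             genome = obj$genome, output_dir = obj$output_dir,
             percentile_rank = obj$percentile_rank,
             normalize_percentile = obj$normalize_percentile,
             normalize_enrichment = obj$normalize_enrichment,
             export_normalized = obj$export_normalized,
             write_gff = obj$write_gff)
}

# Read every coverage file of the layout into library pairs, one pair per
# (condition, replicate, strand, replicon), zero-padding all tracks of one
# replicon to a common length.
load_pairs <- function(layout) {
  files <- layout$files
  missing <- !file.exists(files$path)
  if (any(missing)) {
    m <- files[which(missing)[1], ]
    stop(sprintf("input file missing for slot (%s, %s, %s, %s): %s",
                 m$condition, m$replicate, m$strand, m$library, m$path))
  }
  tracks <- vector("list", nrow(files))
  for (i in seq_len(nrow(files)))
    tracks[[i]] <- read_coverage(files$path[i], strand = files$strand[i])
  replicons <- unique(unlist(lapply(tracks, names)))
  lens <- vapply(replicons, function(r) {
    max(vapply(tracks, function(tt)
      if (r %in% names(tt)) tt[[r]]$length else 0L, numeric(1)))
  }, numeric(1))
  pad <- function(tr, r, strand) {
    L <- as.integer(lens[[r]])
    if (is.null(tr)) return(coverage_track(r, strand, numeric(L)))
    if (tr$length < L)
      tr <- coverage_track(r, strand, c(tr$values, numeric(L - tr$length)))
    tr
  }
  pairs <- list()
  key <- paste(files$condition, files$replicate, files$strand, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    ei <- idx[files$library[idx] == "enriched"]
    ci <- idx[files$library[idx] == "control"]
    for (r in replicons) {
      pairs[[length(pairs) + 1L]] <- library_pair(
        files$condition[ei], files$replicate[ei],
        pad(tracks[[ei]][[r]], r, files$strand[ei]),
        pad(tracks[[ci]][[r]], r, files$strand[ci]))
    }
  }
  pairs
}

#' Run the full TSS prediction pipeline
#'
#' Executes, in order: loading of all coverage pairs, inter-library
#' normalization, per-replicate step detection with window reduction,
#' cross-replicate reconciliation, enrichment filtering, cross-condition
#' clustering and gene-relative classification; then writes the MasterTable,
#' per-condition GFF3 files, optionally the normalized tracks, and a run log
#' with the normalization statistics and per-stage counts. The run is fully
#' deterministic given the configuration.
#'
#' @param config A [run_config].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of class `tss_prediction` with elements `tss`
#'   (the classified `tss_set`), `pairs` (normalized), `norm_stats`,
#'   `candidates` (window-reduced per-replicate candidates), `config` and
#'   `master_table_path`.
#' @export
run_predict <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  params <- config$params
  layout <- config$layout
  for (cn in layout$conditions)
    if (params$min_replicates > length(layout_replicates(layout, cn)))
      stop(sprintf(
        "min_replicates (%d) exceeds the replicate count of condition '%s'",
        params$min_replicates, cn))
  if (!file.exists(config$annotation))
    stop(sprintf("annotation file missing: %s", config$annotation))
  say <- function(...) if (!quiet) message(sprintf(...))

  pairs <- load_pairs(layout)
  say("loaded %d library pairs", length(pairs))
  norm <- normalize_experiment(pairs, config$percentile_rank,
                               percentile = config$normalize_percentile,
                               enrichment = config$normalize_enrichment)
  pairs <- norm$pairs
  height_scale <- if (config$normalize_percentile) norm$stats$q_min else 1
  cands <- detect_all(pairs, params, height_scale)
  say("detected %d window-reduced candidates", nrow(cands))
  tss <- consolidate_tss(cands, pairs, params, height_scale,
                         conditions = layout$conditions)
  say("consolidated to %d enriched TSS", nrow(tss$tss))
  genes <- read_gff(config$annotation)
  tss <- classify_tss(tss, genes, params)

  genome <- NULL
  if (!is.null(config$genome))
    genome <- Biostrings::readDNAStringSet(config$genome)
  out <- config$output_dir
  if (!dir.exists(out) &&
      !dir.create(out, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory %s", out))
  mt_path <- file.path(out, "MasterTable.tsv")
  write_master_table(tss, layout, mt_path, genome = genome)
  if (config$write_gff)
    for (cn in layout$conditions)
      write_gff_output(tss, cn, file.path(out, sprintf("TSS_%s.gff3", cn)))
  if (config$export_normalized)
    write_normalized_tracks(pairs, file.path(out, "normalized"))
  write_run_log(file.path(out, "run.log"), config, norm$stats, cands, tss)

  invisible(structure(
    list(tss = tss, pairs = pairs, norm_stats = norm$stats,
         candidates = cands, config = config,
         master_table_path = mt_path),
    class = "tss_prediction"))
}

write_run_log <- function(path, config, stats, cands, tss) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("tsscall run log")
  p <- config$params
  w("parameters:%s",
    if (!is.null(p$preset)) sprintf(" (preset: %s)", p$preset) else "")
  for (f in setdiff(names(p), "preset"))
    w("  %s = %s", f, format(p[[f]]))
  w("normalization:")
  w("  percentile_rank = %s", format(stats$percentile_rank))
  for (id in names(stats$q_pl))
    w("  Q[%s] = %.6g", id, stats$q_pl[[id]])
  w("  Qmin = %.6g", stats$q_min)
  for (id in names(stats$median_ef))
    w("  medianEF[%s] = %.6g", id, stats$median_ef[[id]])
  w("  EFmax = %.6g", stats$ef_max)
  w("counts:")
  w("  window-reduced candidates = %d", nrow(cands))
  w("  consolidated TSS = %d", nrow(tss$tss))
  w("  enriched condition records = %d", sum(tss$conditions$enriched))
  w("  classifications = %d", nrow(tss$classes))
  invisible(path)
}

#' @export
print.tss_prediction <- function(x, ...) {
  cat(sprintf("<tss_prediction> %d TSS | MasterTable: %s\n",
              nrow(x$tss$tss), x$master_table_path))
  invisible(x)
}

#' Run differential TSS testing from a finished prediction
#'
#' Thin wrapper around [differential_tss()] operating on the result of
#' [run_predict()]; optionally writes the result table as TSV.
#'
#' @param prediction A `tss_prediction`.
#' @param condition_a,condition_b Conditions to compare.
#' @param half_window Window half width in bp (default 50).
#' @param path Optional output TSV path.
#' @return The [differential_tss()] data.frame.
#' @export
run_differential <- function(prediction, condition_a, condition_b,
                             half_window = 50L, path = NULL) {
  stopifnot(inherits(prediction, "tss_prediction"))
  res <- differential_tss(prediction$tss, prediction$pairs,
                          condition_a, condition_b, half_window)
  if (!is.null(path))
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}
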