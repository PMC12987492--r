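#' Parameter set for TSS calling
#'
#' Bundles every tunable threshold of the pipeline. The three detection
#' thresholds (`step_height`, `step_factor`, `enrichment_factor`) can be
#' loaded as one of five named presets, ordered from most sensitive to most
#' specific (see [tss_presets()]).
#'
#' `step_height` and `step_height_reduction` are expressed relative to the
#' percentile value used for inter-library normalization: a threshold of 0.3
#' means 0.3 x Qmin in normalized coverage units, so the same nominal
#' threshold adapts to the depth of the experiment. When normalization is
#' disabled the scale factor is 1 and the threshold is absolute.
#'
#' @param preset Optional preset name (`"very sensitive"`, `"sensitive"`,
#'   `"default"`, `"specific"`, `"very specific"`; hyphens/underscores also
#'   accepted). Sets the three thresholds and the two reduction values;
#'   explicit arguments override preset values.
#' @param step_height Minimum step height `e(i) - e(i-1)` for a candidate,
#'   relative to the normalization percentile (>= 0).
#' @param step_factor Minimum step factor `e(i) / e(i-1)` (>= 1).
#' @param enrichment_factor Minimum enriched/control ratio for a detected TSS
#'   to be called enriched (>= 1).
#' @param step_height_reduction,step_factor_reduction Amounts subtracted from
#'   the two detection thresholds when re-evaluating a TSS position in a
#'   replicate that missed it (floored at 0 and 1 respectively).
#' @param window Window size W (bp) for reducing clusters of nearby
#'   candidates within one replicate; 0 disables reduction.
#' @param reduction_mode How a cluster of close candidates is collapsed:
#'   `"strongest"` keeps the largest step height, `"first"` the 5'-most
#'   position (strand aware).
#' @param cross_replicate_shift Maximum distance (bp) at which detections in
#'   different replicates are considered the same TSS (default 1).
#' @param cross_condition_shift Maximum distance (bp) at which enriched TSS of
#'   different conditions are considered equal (default 1).
#' @param min_replicates Minimum number of detecting replicates Rmin for a
#'   TSS to be kept (default 1).
#' @param utr_length Maximum distance (bp) upstream of an annotated
#'   translation start at which a TSS can be primary/secondary (default 300).
#' @param antisense_distance Maximum distance (bp) from a gene on the opposite
#'   strand for the antisense class (default 150, boundary included).
#' @param primary_rule `"strongest"` (largest enriched step height wins, ties
#'   to the shortest UTR) or `"first"` (5'-most upstream TSS is primary).
#' @return An object of class `tss_params` (a validated list).
#' @examples
#' tss_params(preset = "very specific", cross_condition_shift = 3,
#'            cross_replicate_shift = 2)
#' @export
tss_params <- function(preset = NULL,
                       step_height = 0.3,
                       step_factor = 2.0,
                       enrichment_factor = 2.0,
                       step_height_reduction = 0.2,
                       step_factor_reduction = 0.5,
                       window = 3L,
                       reduction_mode = c("strongest", "first"),
                       cross_replicate_shift = 1L,
                       cross_condition_shift = 1L,
                       min_replicates = 1L,
                       utr_length = 300L,
                       antisense_distance = 150L,
                       primary_rule = c("strongest", "first")) {
  reduction_mode <- match.arg(reduction_mode)
  primary_rule <- match.arg(primary_rule)
  if (!is.null(preset)) {
    row <- resolve_preset(preset)
    if (missing(step_height)) step_height <- row$step_height
    if (missing(step_factor)) step_factor <- row$step_factor
    if (missing(enrichment_factor)) enrichment_factor <- row$enrichment_factor
    if (missing(step_height_reduction))
      step_height_reduction <- row$step_height_reduction
    if (missing(step_factor_reduction))
      step_factor_reduction <- row$step_factor_reduction
    preset <- row$preset
  }
  p <- structure(
    list(preset = preset,
         step_height = as.numeric(step_height),
         step_factor = as.numeric(step_factor),
         enrichment_factor = as.numeric(enrichment_factor),
         step_height_reduction = as.numeric(step_height_reduction),
         step_factor_reduction = as.numeric(step_factor_reduction),
         window = as.integer(window),
         reduction_mode = reduction_mode,
         cross_replicate_shift = as.integer(cross_replicate_shift),
         cross_condition_shift = as.integer(cross_condition_shift),
         min_replicates = as.integer(min_replicates),
         utr_length = as.integer(utr_length),
         antisense_distance = as.integer(antisense_distance),
         primary_rule = primary_rule),
    class = "tss_params"
  )
  validate_params(p)
  p
}

validate_params <- function(p) {
  with(p, {
    if (step_height < 0) stop("step_height must be >= 0")
    if (step_factor < 1) stop("step_factor must be >= 1")
    if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
    if (step_height_reduction < 0 || step_height_reduction > step_height)
      stop("step_height_reduction must lie in [0, step_height]")
    if (step_factor_reduction < 0 || step_factor_reduction > step_factor - 1)
      stop("step_factor_reduction must lie in [0, step_factor - 1]")
    if (window < 0) stop("window must be >= 0")
    if (cross_replicate_shift < 0 || cross_condition_shift < 0)
      stop("shift values must be >= 0")
    if (min_replicates < 1) stop("min_replicates must be >= 1")
  })
  invisible(p)
}

#' @export
print.tss_params <- function(x, ...) {
  cat("<tss_params>",
      if (!is.null(x$preset)) sprintf(" preset: %s", x$preset) else "", "\n",
      sep = "")
  flds <- setdiff(names(x), "preset")
  for (f in flds) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Predefined detection threshold presets
#'
#' Five named threshold sets, ordered from most sensitive (lowest thresholds,
#' most candidate TSS) to most specific. The table ships as a plain TSV in the
#' package (`inst/extdata/presets.tsv`) so the shipped values can be inspected
#' or adjusted without touching code.
#'
#' @return A data.frame with one row per preset and columns `preset`,
#'   `step_height`, `step_height_reduction`, `step_factor`,
#'   `step_factor_reduction`, `enrichment_factor`.
#' @export
tss_presets <- function() {
  path <- system.file("extdata", "presets.tsv", package = "tsscall",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

resolve_preset <- function(name) {
  tab <- tss_presets()
  key <- gsub("[-_]+", " ", tolower(trimws(name)))
  hit <- match(key, tab$preset)
  if (is.na(hit))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(tab$preset, collapse = ", ")))
  as.list(tab[hit, ])
}
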