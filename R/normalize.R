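#' @name normalize
#' @title Two-stage inter-library normalization
#'
#' @description
#' Library pairs from different replicates and conditions are made comparable
#' in two stages. First, *percentile normalization*: for each pair the
#' `percentile_rank` quantile (default the 90th percentile, computed over the
#' non-zero positions of the enriched track) is taken as that pair's scale
#' `Q_PL`; both tracks of the pair are multiplied by `Q_min / Q_PL`, where
#' `Q_min` is the smallest percentile value across pairs, so every enriched
#' library ends up with the same percentile value while the data stay on the
#' scale of the shallowest library. Second, *enrichment-factor equalization*:
#' per pair the median of the per-position ratio enriched/control (over
#' positions where both are positive) is computed; each control track is
#' multiplied by `median_EF / EF_max`, after which every pair presents the
#' same apparent enrichment `EF_max`. Shrinking the control rather than
#' inflating it keeps the enriched tracks — the ones detection runs on —
#' untouched by the second stage.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) and are taken over non-zero positions only:
#' prokaryotic coverage is sparse, and a percentile over all positions would
#' often be zero, degenerating the scheme.
NULL

new_norm_stats <- function(percentile_rank) {
  structure(list(percentile_rank = percentile_rank,
                 q_pl = numeric(0), q_min = NA_real_,
                 median_ef = numeric(0), ef_max = NA_real_),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat(sprintf("<norm_stats> rank %.2f | Qmin %.6g | EFmax %.6g\n",
              x$percentile_rank, x$q_min, x$ef_max))
  invisible(x)
}

enriched_percentile <- function(pair, rank) {
  v <- pair$enriched$values
  v <- v[v > 0]
  if (length(v) == 0L) return(0)
  unname(stats::quantile(v, rank, names = FALSE, type = 7))
}

#' Percentile normalization of library pairs
#'
#' @param pairs List of [library_pair] objects.
#' @param percentile_rank Quantile rank in (0, 1]; default 0.9.
#' @param stats Optional pre-allocated `norm_stats` to fill in.
#' @return A list with elements `pairs` (rescaled) and `stats` (a
#'   `norm_stats` with `q_pl` per pair and `q_min`).
#' @seealso [normalize] for the scheme.
#' @export
percentile_normalize <- function(pairs, percentile_rank = 0.9,
                                 stats = NULL) {
  stopifnot(length(pairs) > 0, percentile_rank > 0, percentile_rank <= 1)
  if (is.null(stats)) stats <- new_norm_stats(percentile_rank)
  ids <- vapply(pairs, pair_id, character(1))
  q <- vapply(pairs, enriched_percentile, numeric(1),
              rank = percentile_rank)
  names(q) <- ids
  if (any(q == 0)) {
    bad <- ids[q == 0][1]
    stop(sprintf(
      "percentile normalization failed: enriched library of pair '%s' has percentile 0 (degenerate library)",
      bad))
  }
  qmin <- min(q)
  for (k in seq_along(pairs)) {
    f <- qmin / q[k]
    pairs[[k]]$enriched$values <- pairs[[k]]$enriched$values * f
    pairs[[k]]$control$values <- pairs[[k]]$control$values * f
  }
  stats$q_pl <- q
  stats$q_min <- qmin
  list(pairs = pairs, stats = stats)
}

median_enrichment_factor <- function(pair) {
  e <- pair$enriched$values
  n <- pair$control$values
  both <- e > 0 & n > 0
  if (!any(both)) return(NA_real_)
  stats::median(e[both] / n[both])
}

#' Enrichment-factor equalization of control libraries
#'
#' @param pairs List of [library_pair] objects, percentile-normalized.
#' @param stats `norm_stats` from [percentile_normalize()] (or a fresh one).
#' @return A list with elements `pairs` and `stats` (with `median_ef` per
#'   pair and `ef_max` filled in).
#' @export
enrichment_normalize <- function(pairs, stats = NULL) {
  stopifnot(length(pairs) > 0)
  if (is.null(stats)) stats <- new_norm_stats(NA_real_)
  ids <- vapply(pairs, pair_id, character(1))
  ef <- vapply(pairs, median_enrichment_factor, numeric(1))
  names(ef) <- ids
  if (anyNA(ef)) {
    bad <- ids[is.na(ef)][1]
    stop(sprintf(
      "enrichment normalization failed: pair '%s' has no position where both libraries are positive",
      bad))
  }
  efmax <- max(ef)
  for (k in seq_along(pairs))
    pairs[[k]]$control$values <- pairs[[k]]$control$values * (ef[k] / efmax)
  stats$median_ef <- ef
  stats$ef_max <- efmax
  list(pairs = pairs, stats = stats)
}

#' Run the full inter-library normalization
#'
#' Applies [percentile_normalize()] then [enrichment_normalize()]; either
#' stage can be disabled. The returned statistics carry `q_min`, which the
#' detection stage uses to put the (relative) step-height threshold on the
#' normalized coverage scale.
#'
#' @param pairs List of [library_pair] objects.
#' @param percentile_rank Quantile rank for the first stage (default 0.9).
#' @param percentile,enrichment Logical switches for the two stages.
#' @return A list with elements `pairs` and `stats`.
#' @export
normalize_experiment <- function(pairs, percentile_rank = 0.9,
                                 percentile = TRUE, enrichment = TRUE) {
  stats <- new_norm_stats(if (percentile) percentile_rank else NA_real_)
  if (percentile) {
    res <- percentile_normalize(pairs, percentile_rank, stats)
    pairs <- res$pairs; stats <- res$stats
  }
  if (enrichment) {
    res <- enrichment_normalize(pairs, stats)
    pairs <- res$pairs; stats <- res$stats
  }
  list(pairs = pairs, stats = stats)
}
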