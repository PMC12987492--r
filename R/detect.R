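#' Detect TSS candidates in one library pair
#'
#' Scans the enriched track of a pair position by position. A position `i` is
#' a candidate when both the step height `e(i) - e(prev)` and the step factor
#' `e(i) / e(prev)` reach their thresholds, where `prev` is the neighbouring
#' position 5' of `i` in transcript orientation (see [step_metrics()]). The
#' control track plays no role at this stage; enrichment is tested later, on
#' the consolidated candidates.
#'
#' The step-height threshold is relative to the normalization percentile:
#' the effective absolute threshold is `params$step_height * height_scale`,
#' with `height_scale` the `q_min` recorded by [normalize_experiment()] (1
#' when normalization is off, making the threshold absolute).
#'
#' @param pair A normalized [library_pair].
#' @param params A [tss_params] object.
#' @param height_scale Scale for the relative step-height threshold
#'   (default 1).
#' @return A data.frame of candidates with columns `replicon_id`, `position`,
#'   `strand`, `step_height`, `step_factor`, `condition`, `replicate`.
#' @export
detect_candidates <- function(pair, params, height_scale = 1) {
  stopifnot(inherits(pair, "library_pair"), inherits(params, "tss_params"))
  e <- pair$enriched$values
  prev <- previous_values(e, pair$strand)
  height <- e - prev
  factor <- step_factor_from(e, prev)
  h_thr <- params$step_height * height_scale
  keep <- which(height >= h_thr & factor >= params$step_factor & e > 0)
  data.frame(
    replicon_id = rep(pair$replicon_id, length(keep)),
    position = keep,
    strand = rep(pair$strand, length(keep)),
    step_height = height[keep],
    step_factor = factor[keep],
    condition = rep(pair$condition, length(keep)),
    replicate = rep(pair$replicate, length(keep)),
    stringsAsFactors = FALSE)
}

#' Collapse clusters of nearby candidates
#'
#' Candidates on one strand are grouped into maximal runs in which consecutive
#' members are at most `W` bp apart (chaining); each run is reduced to a
#' single survivor — the one with the largest step height
#' (`mode = "strongest"`, ties to the smallest coordinate) or the 5'-most one
#' (`mode = "first"`: smallest coordinate on the forward strand, largest on
#' the reverse). `W = 0` leaves the input unchanged. Survivors of one run are
#' by construction more than `W` bp apart, and the operation is idempotent.
#'
#' @param cands Candidate data.frame from [detect_candidates()] (one strand
#'   and replicon).
#' @param W Window size in bp.
#' @param mode `"strongest"` or `"first"`.
#' @return The reduced candidate data.frame, sorted by position.
#' @export
reduce_close_candidates <- function(cands, W,
                                    mode = c("strongest", "first")) {
  mode <- match.arg(mode)
  if (nrow(cands) <= 1L || W == 0L)
    return(cands[order(cands$position), , drop = FALSE])
  if (length(unique(cands$strand)) > 1L ||
      length(unique(cands$replicon_id)) > 1L)
    stop("reduce_close_candidates expects candidates of one strand/replicon")
  cands <- cands[order(cands$position), , drop = FALSE]
  run <- cumsum(c(TRUE, diff(cands$position) > W))
  keep <- vapply(split(seq_len(nrow(cands)), run), function(idx) {
    if (length(idx) == 1L) return(idx)
    if (mode == "strongest") {
      idx[which.max(cands$step_height[idx])]  # first max = smallest coord
    } else if (cands$strand[idx[1]] == "+") {
      idx[1L]
    } else {
      idx[length(idx)]
    }
  }, integer(1))
  out <- cands[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(replicon_id = character(), position = integer(),
             strand = character(), step_height = numeric(),
             step_factor = numeric(), condition = character(),
             replicate = character(), stringsAsFactors = FALSE)
}

#' Detect and window-reduce candidates for a set of pairs
#'
#' Convenience wrapper: runs [detect_candidates()] followed by
#' [reduce_close_candidates()] per pair and binds the results.
#'
#' @inheritParams detect_candidates
#' @param pairs List of normalized [library_pair] objects.
#' @return A single candidate data.frame.
#' @export
detect_all <- function(pairs, params, height_scale = 1) {
  res <- lapply(pairs, function(p) {
    cc <- detect_candidates(p, params, height_scale)
    reduce_close_candidates(cc, params$window, params$reduction_mode)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(empty_candidates())
  rownames(out) <- NULL
  out
}
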