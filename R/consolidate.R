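chain_clusters <- function(positions, gap) {
  # maximal runs in which consecutive sorted positions are <= gap apart
  if (length(positions) == 0L) return(integer(0))
  cumsum(c(TRUE, diff(positions) > gap))
}

find_pair <- function(pairs, condition, replicate, strand, replicon) {
  for (p in pairs)
    if (p$condition == condition && p$replicate == replicate &&
        p$strand == strand && p$replicon_id == replicon)
      return(p)
  NULL
}

# Best position within [lo, hi] of a track that passes the (reduced)
# thresholds; NULL if none qualifies.
best_qualifying <- function(pair, lo, hi, h_thr, f_thr) {
  lo <- max(1L, lo); hi <- min(pair$enriched$length, hi)
  if (lo > hi) return(NULL)
  m <- step_metrics(pair$enriched, lo:hi)
  e <- pair$enriched$values[lo:hi]
  ok <- which(m$height >= h_thr & m$factor >= f_thr & e > 0)
  if (length(ok) == 0L) return(NULL)
  best <- ok[which.max(m$height[ok])]
  list(position = (lo:hi)[best], step_height = m$height[best],
       step_factor = m$factor[best])
}

#' Reconcile TSS candidates across replicates of one condition
#'
#' Candidates from different replicates within `cross_replicate_shift` bp of
#' each other are identified as the same TSS. For every replicate that missed
#' an identified TSS, the positions within the shift window are re-evaluated
#' against reduced thresholds (`step_height - step_height_reduction`, floored
#' at 0; `step_factor - step_factor_reduction`, floored at 1), and a
#' qualifying position counts as a detection. A TSS is kept when at least
#' `min_replicates` replicates detect it.
#'
#' @param cands Window-reduced candidate data.frame of one condition.
#' @param pairs Normalized [library_pair] list of the same condition (used for
#'   re-evaluation).
#' @param params A [tss_params].
#' @param height_scale Scale of the relative step-height threshold (see
#'   [detect_candidates()]).
#' @return A data.frame with one row per surviving TSS: `replicon_id`,
#'   `strand`, `position` (strongest detection, ties to the smallest
#'   coordinate), `condition`, `det_count`, `step_height`, `step_factor`.
#' @export
reconcile_replicates <- function(cands, pairs, params, height_scale = 1) {
  stopifnot(inherits(params, "tss_params"))
  condition <- unique(c(cands$condition,
                        vapply(pairs, function(p) p$condition, character(1))))
  if (length(condition) != 1L)
    stop("reconcile_replicates expects candidates/pairs of one condition")
  replicates <- unique(vapply(pairs, function(p) p$replicate, character(1)))
  if (params$min_replicates > length(replicates))
    stop(sprintf("min_replicates (%d) exceeds the number of replicates (%d)",
                 params$min_replicates, length(replicates)))
  dr <- params$cross_replicate_shift
  h_red <- max(params$step_height - params$step_height_reduction, 0) *
    height_scale
  f_red <- max(params$step_factor - params$step_factor_reduction, 1)
  out <- list()
  groups <- split(seq_len(nrow(cands)),
                  paste(cands$replicon_id, cands$strand, sep = "\r"))
  for (idx in groups) {
    sub <- cands[idx, , drop = FALSE]
    sub <- sub[order(sub$position, -sub$step_height), , drop = FALSE]
    cl <- chain_clusters(sub$position, dr)
    for (members in split(seq_len(nrow(sub)), cl)) {
      mm <- sub[members, , drop = FALSE]
      best <- which.max(mm$step_height)
      rep_pos <- mm$position[best]
      dets <- data.frame(replicate = mm$replicate,
                         position = mm$position,
                         step_height = mm$step_height,
                         step_factor = mm$step_factor,
                         stringsAsFactors = FALSE)
      for (r in setdiff(replicates, unique(mm$replicate))) {
        pr <- find_pair(pairs, condition, r, mm$strand[1], mm$replicon_id[1])
        if (is.null(pr)) next
        hit <- best_qualifying(pr, rep_pos - dr, rep_pos + dr, h_red, f_red)
        if (!is.null(hit))
          dets <- rbind(dets, data.frame(replicate = r,
                                         position = hit$position,
                                         step_height = hit$step_height,
                                         step_factor = hit$step_factor,
                                         stringsAsFactors = FALSE))
      }
      det_count <- length(unique(dets$replicate))
      if (det_count < params$min_replicates) next
      top <- order(-dets$step_height, dets$position)[1]
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = mm$replicon_id[1], strand = mm$strand[1],
        position = dets$position[top], condition = condition,
        det_count = det_count,
        step_height = dets$step_height[top],
        step_factor = dets$step_factor[top],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(replicon_id = character(), strand = character(),
                      position = integer(), condition = character(),
                      det_count = integer(), step_height = numeric(),
                      step_factor = numeric(), stringsAsFactors = FALSE)
  res <- res[order(res$replicon_id, res$strand, res$position,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Per-replicate enrichment factors at one position; NA when both libraries
# are zero there.
replicate_efs <- function(pairs, condition, strand, replicon, position) {
  efs <- numeric(0)
  for (p in pairs) {
    if (p$condition != condition || p$strand != strand ||
        p$replicon_id != replicon) next
    if (position < 1L || position > p$enriched$length) next
    e <- p$enriched$values[position]
    n <- p$control$values[position]
    efs <- c(efs, if (n > 0) e / n else if (e > 0) Inf else NA_real_)
  }
  efs
}

annotate_enrichment <- function(detected, pairs, params) {
  n <- nrow(detected)
  ef <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    efs <- replicate_efs(pairs, detected$condition[i], detected$strand[i],
                         detected$replicon_id[i], detected$position[i])
    efs <- efs[!is.na(efs)]
    if (length(efs)) ef[i] <- max(efs)
  }
  detected$enrichment_factor <- ef
  detected$enriched <- !is.na(ef) & ef >= params$enrichment_factor
  detected
}

#' Filter detected TSS by enrichment against the control library
#'
#' For every detected TSS the enrichment factor `EF = e_enr(j) / e_non(j)` is
#' evaluated at the TSS position in each replicate of its condition (`Inf`
#' when the control is zero but the enriched value positive; undefined and
#' excluded when both are zero). The maximum across replicates is compared to
#' the threshold: at `enrichment_factor = 2`, double the control expression is
#' required. Only enriched TSS are returned.
#'
#' @param detected Output of [reconcile_replicates()] (any number of
#'   conditions).
#' @param pairs Normalized [library_pair] list covering those conditions.
#' @param params A [tss_params].
#' @return The enriched subset, with columns `enrichment_factor` and
#'   `enriched` (all `TRUE`) appended.
#' @export
enrichment_filter <- function(detected, pairs, params) {
  ann <- annotate_enrichment(detected, pairs, params)
  out <- ann[ann$enriched, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_tss_set <- function(conditions) {
  structure(list(
    tss = data.frame(tss_id = integer(), replicon_id = character(),
                     strand = character(), position = integer(),
                     stringsAsFactors = FALSE),
    conditions = data.frame(tss_id = integer(), condition = character(),
                            detected = logical(), enriched = logical(),
                            position = integer(), det_count = integer(),
                            step_height = numeric(), step_factor = numeric(),
                            enrichment_factor = numeric(),
                            stringsAsFactors = FALSE),
    classes = data.frame(tss_id = integer(), tss_class = character(),
                         locus_tag = character(), gene_name = character(),
                         product = character(), utr_length = integer(),
                         gene_length = integer(), offset = integer(),
                         stringsAsFactors = FALSE),
    condition_names = conditions), class = "tss_set")
}

#' @export
print.tss_set <- function(x, ...) {
  cat(sprintf("<tss_set> %d TSS, %d condition(s)%s\n", nrow(x$tss),
              length(x$condition_names),
              if (nrow(x$classes)) sprintf(", %d classification(s)",
                                           nrow(x$classes)) else ""))
  invisible(x)
}

#' Cluster enriched TSS across conditions
#'
#' Enriched TSS of different conditions within `cross_condition_shift` bp
#' (single-linkage chaining per replicon and strand) are considered one TSS.
#' The cluster representative is the contributing position with the largest
#' step height (ties to the smallest coordinate). Two TSS of the same
#' condition landing in one cluster are collapsed to the stronger, with a
#' warning. When the annotated `detected` table is supplied, conditions that
#' detected (but did not enrich) a TSS within the shift window of the
#' representative are recorded as `detected = TRUE, enriched = FALSE`; all
#' remaining conditions get an explicit absent record.
#'
#' @param enriched Output of [enrichment_filter()], all conditions pooled.
#' @param params A [tss_params].
#' @param detected Optional annotated detected table (from
#'   [reconcile_replicates()] run through the enrichment annotation) used to
#'   fill in detected-only conditions.
#' @param conditions Character vector of all experiment conditions (defaults
#'   to those present in `enriched`/`detected`).
#' @return A `tss_set`: list of data.frames `tss` (cluster representatives),
#'   `conditions` (per-condition records) and `classes` (empty until
#'   [classify_tss()]).
#' @export
cluster_across_conditions <- function(enriched, params, detected = NULL,
                                      conditions = NULL) {
  stopifnot(inherits(params, "tss_params"))
  if (is.null(conditions))
    conditions <- unique(c(enriched$condition, detected$condition))
  out <- empty_tss_set(conditions)
  if (nrow(enriched) == 0L) return(out)
  shift <- params$cross_condition_shift
  tss_rows <- list(); cond_rows <- list()
  groups <- split(seq_len(nrow(enriched)),
                  paste(enriched$replicon_id, enriched$strand, sep = "\r"))
  for (idx in groups) {
    sub <- enriched[idx, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    cl <- chain_clusters(sub$position, shift)
    for (members in split(seq_len(nrow(sub)), cl)) {
      mm <- sub[members, , drop = FALSE]
      if (anyDuplicated(mm$condition)) {
        warning(sprintf(
          "two enriched TSS of condition '%s' fell into one cluster near %s:%d; keeping the stronger",
          mm$condition[which(duplicated(mm$condition))[1]],
          mm$replicon_id[1], mm$position[1]))
        keep <- unlist(lapply(split(seq_len(nrow(mm)), mm$condition),
                              function(ii)
                                ii[order(-mm$step_height[ii],
                                         mm$position[ii])[1]]))
        mm <- mm[sort(unname(keep)), , drop = FALSE]
      }
      best <- order(-mm$step_height, mm$position)[1]
      rep_pos <- mm$position[best]
      cond_rec <- data.frame(
        condition = mm$condition, detected = TRUE, enriched = TRUE,
        position = mm$position, det_count = mm$det_count,
        step_height = mm$step_height, step_factor = mm$step_factor,
        enrichment_factor = mm$enrichment_factor, stringsAsFactors = FALSE)
      for (cn in setdiff(conditions, mm$condition)) {
        extra <- NULL
        if (!is.null(detected)) {
          dd <- detected[detected$condition == cn &
                           detected$replicon_id == mm$replicon_id[1] &
                           detected$strand == mm$strand[1] &
                           abs(detected$position - rep_pos) <= shift &
                           !detected$enriched, , drop = FALSE]
          if (nrow(dd)) {
            dd <- dd[order(-dd$step_height, dd$position)[1], , drop = FALSE]
            extra <- data.frame(
              condition = cn, detected = TRUE, enriched = FALSE,
              position = dd$position, det_count = dd$det_count,
              step_height = dd$step_height, step_factor = dd$step_factor,
              enrichment_factor = dd$enrichment_factor,
              stringsAsFactors = FALSE)
          }
        }
        if (is.null(extra))
          extra <- data.frame(
            condition = cn, detected = FALSE, enriched = FALSE,
            position = rep_pos, det_count = 0L,
            step_height = NA_real_, step_factor = NA_real_,
            enrichment_factor = NA_real_, stringsAsFactors = FALSE)
        cond_rec <- rbind(cond_rec, extra)
      }
      tss_rows[[length(tss_rows) + 1L]] <- data.frame(
        replicon_id = mm$replicon_id[1], strand = mm$strand[1],
        position = rep_pos, stringsAsFactors = FALSE)
      cond_rows[[length(cond_rows) + 1L]] <- cond_rec
    }
  }
  tss <- do.call(rbind, tss_rows)
  ord <- order(tss$replicon_id, tss$strand, tss$position,
               method = "radix")
  tss <- tss[ord, , drop = FALSE]
  tss$tss_id <- seq_len(nrow(tss))
  rownames(tss) <- NULL
  conds <- do.call(rbind, lapply(seq_along(ord), function(k) {
    cbind(tss_id = k, cond_rows[[ord[k]]])
  }))
  conds$condition <- factor(conds$condition, levels = conditions)
  conds <- conds[order(conds$tss_id, conds$condition), , drop = FALSE]
  conds$condition <- as.character(conds$condition)
  rownames(conds) <- NULL
  out$tss <- tss[c("tss_id", "replicon_id", "strand", "position")]
  out$conditions <- conds
  out$condition_names <- conditions
  out
}

#' Consolidate per-replicate candidates into a cross-condition TSS set
#'
#' Runs [reconcile_replicates()] per condition, annotates enrichment, keeps
#' enriched TSS and clusters them across conditions — the full consolidation
#' of window-reduced candidates into a `tss_set`.
#'
#' @param cands Candidate data.frame from [detect_all()] (all conditions).
#' @param pairs Normalized [library_pair] list (all conditions).
#' @param params A [tss_params].
#' @param height_scale See [detect_candidates()].
#' @param conditions All experiment condition names, in order.
#' @return A `tss_set` (classifications not yet assigned).
#' @export
consolidate_tss <- function(cands, pairs, params, height_scale = 1,
                            conditions = NULL) {
  pair_conditions <- unique(vapply(pairs, function(p) p$condition,
                                   character(1)))
  if (is.null(conditions)) conditions <- pair_conditions
  detected <- do.call(rbind, lapply(pair_conditions, function(cn) {
    reconcile_replicates(cands[cands$condition == cn, , drop = FALSE],
                         pairs[vapply(pairs, function(p)
                           p$condition == cn, logical(1))],
                         params, height_scale)
  }))
  if (is.null(detected) || nrow(detected) == 0L)
    return(empty_tss_set(conditions))
  detected <- annotate_enrichment(detected, pairs, params)
  enriched <- detected[detected$enriched, , drop = FALSE]
  cluster_across_conditions(enriched, params, detected = detected,
                            conditions = conditions)
}
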