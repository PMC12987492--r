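#' UpSet-style subset counts over TSS classes or conditions
#'
#' Summarizes how TSS distribute over combinations of class labels or of
#' conditions, in the form consumed by UpSet plots: a count per non-empty
#' label set.
#'
#' With `mode = "by_class"` the label set of a TSS is its set of assigned
#' classes. Under `aggregation = "position_only"` each distinct TSS
#' (position and strand) is counted once; under `"position_and_condition"`
#' each (TSS, condition) pair in which the TSS is enriched is counted
#' separately, so a TSS enriched in three conditions contributes three units.
#' With `mode = "by_condition"` the label set is the set of conditions in
#' which the TSS is enriched, and each TSS counts once.
#'
#' @param tss A classified `tss_set`.
#' @param mode `"by_class"` or `"by_condition"`.
#' @param aggregation `"position_only"` or `"position_and_condition"`
#'   (`by_class` mode only).
#' @param classes Optional class filter (e.g. `"primary"` to study the
#'   condition combinations of primary TSS only).
#' @return A data.frame with columns `subset` (labels joined by `&`, sorted)
#'   and `count`; total count equals the number of aggregated units.
#' @export
subset_counts <- function(tss, mode = c("by_class", "by_condition"),
                          aggregation = c("position_only",
                                          "position_and_condition"),
                          classes = NULL) {
  mode <- match.arg(mode)
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(tss, "tss_set"))
  empty <- data.frame(subset = character(), count = integer(),
                      stringsAsFactors = FALSE)
  ids <- tss$tss$tss_id
  if (!is.null(classes)) {
    keep <- unique(tss$classes$tss_id[tss$classes$tss_class %in% classes])
    ids <- intersect(ids, keep)
  }
  if (length(ids) == 0L) return(empty)
  labels <- character(0)
  if (mode == "by_class") {
    sets <- vapply(ids, function(id) {
      cl <- sort(unique(tss$classes$tss_class[tss$classes$tss_id == id]),
                 method = "radix")
      paste(cl, collapse = "&")
    }, character(1))
    if (aggregation == "position_and_condition") {
      reps <- vapply(ids, function(id)
        sum(tss$conditions$enriched[tss$conditions$tss_id == id]),
        integer(1))
      sets <- rep(sets, reps)
    }
    labels <- sets
  } else {
    labels <- vapply(ids, function(id) {
      cc <- tss$conditions[tss$conditions$tss_id == id &
                             tss$conditions$enriched, , drop = FALSE]
      paste(sort(cc$condition, method = "radix"), collapse = "&")
    }, character(1))
    labels <- labels[nzchar(labels)]
  }
  if (length(labels) == 0L) return(empty)
  tab <- table(labels)
  data.frame(subset = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract coverage windows around TSS positions
#'
#' For each requested TSS and each replicate of each condition, the enriched
#' coverage at positions within `half_window` bp of the TSS is extracted,
#' oriented in transcript direction (reverse-strand windows are flipped so
#' that positive offsets are downstream), and renormalized to sum 1 so the
#' window can be treated as an empirical distribution over offsets. The raw
#' coverage mass is kept as the `mass` element — it supplies the effective
#' sample size of the KS test.
#'
#' @param tss A `tss_set`.
#' @param pairs Normalized [library_pair] list.
#' @param half_window Half window width in bp (default 50).
#' @param conditions Conditions to extract (default: all).
#' @return A nested list: `[[tss_id as character]][[condition]][[replicate]]`
#'   is a list with `weights` (length `2*half_window+1`, summing to 1) and
#'   `mass`, or `NULL` for an all-zero window (with a warning). Windows
#'   reaching past a replicon boundary are zero-padded with a warning.
#' @export
extract_profiles <- function(tss, pairs, half_window = 50L,
                             conditions = NULL) {
  stopifnot(inherits(tss, "tss_set"), half_window >= 1L)
  if (is.null(conditions)) conditions <- tss$condition_names
  out <- list()
  for (i in seq_len(nrow(tss$tss))) {
    id <- as.character(tss$tss$tss_id[i])
    pos <- tss$tss$position[i]
    std <- tss$tss$strand[i]
    rep_id <- tss$tss$replicon_id[i]
    out[[id]] <- list()
    for (p in pairs) {
      if (!(p$condition %in% conditions) || p$strand != std ||
          p$replicon_id != rep_id) next
      L <- p$enriched$length
      lo <- pos - half_window; hi <- pos + half_window
      if (lo < 1L || hi > L)
        warning(sprintf(
          "window around TSS %s:%d exceeds replicon boundary; truncated",
          rep_id, pos))
      idx <- pmax(pmin(lo:hi, L), 1L)
      w <- p$enriched$values[idx]
      w[lo:hi < 1L | lo:hi > L] <- 0
      if (std == "-") w <- rev(w)  # positive offset = downstream
      mass <- sum(w)
      out[[id]][[p$condition]][[p$replicate]] <-
        if (mass > 0) list(weights = w / mass, mass = mass) else NULL
      if (mass == 0)
        warning(sprintf(
          "all-zero window around TSS %s:%d in %s/%s; profile undefined",
          rep_id, pos, p$condition, p$replicate))
    }
  }
  out
}

# Asymptotic two-sample KS p-value: P(sqrt(n_eff) * D) via the Kolmogorov
# distribution tail sum.
ks_asymptotic_p <- function(D, n_eff) {
  t <- sqrt(n_eff) * D
  if (t < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

weighted_ks_stat <- function(a, b) {
  if (length(a$weights) != length(b$weights))
    stop("windows must have equal length")
  max(abs(cumsum(a$weights) - cumsum(b$weights)))
}

#' Pairwise KS tests between two conditions' coverage windows
#'
#' Compares the offset-distributions of the enriched coverage around one TSS
#' between every (replicate of A, replicate of B) combination, using the
#' two-sample Kolmogorov–Smirnov statistic on the weighted empirical CDFs
#' (coverage mass as weights; deterministic — no resampling of reads). The
#' p-value comes from the asymptotic KS distribution with effective sample
#' size `n1*n2/(n1+n2)`, where `n_i` is the rounded coverage mass of the
#' window, capped at 10,000.
#'
#' @param windows_a,windows_b Named lists of windows (one per replicate) as
#'   produced by [extract_profiles()]; `NULL` (degenerate) windows are
#'   excluded with a warning.
#' @return A numeric vector of p-values, one per replicate pair, named
#'   `repA|repB`; length 0 if no valid pair exists.
#' @export
pairwise_ks <- function(windows_a, windows_b) {
  drop_null <- function(w, lab) {
    bad <- vapply(w, is.null, logical(1))
    if (any(bad))
      warning(sprintf("excluding %d degenerate window(s) in %s",
                      sum(bad), lab))
    w[!bad]
  }
  windows_a <- drop_null(windows_a, "condition A")
  windows_b <- drop_null(windows_b, "condition B")
  ps <- numeric(0)
  for (ra in names(windows_a)) for (rb in names(windows_b)) {
    a <- windows_a[[ra]]; b <- windows_b[[rb]]
    D <- weighted_ks_stat(a, b)
    n1 <- min(round(a$mass), 10000)
    n2 <- min(round(b$mass), 10000)
    n_eff <- n1 * n2 / (n1 + n2)
    ps[paste(ra, rb, sep = "|")] <- ks_asymptotic_p(D, n_eff)
  }
  ps
}

#' Cauchy combination of p-values
#'
#' Combines `k` dependent or independent p-values into one:
#' `T = mean(tan((0.5 - p) * pi))`, `combined = 0.5 - atan(T) / pi`.
#' Inputs are clipped away from 0 and 1 by 1e-15 before the tangent. The
#' transform is permutation invariant and fixes constant inputs
#' (`cauchy_combine(rep(p, k)) == p`).
#'
#' @param pvalues Numeric vector of p-values in (0, 1); length >= 1.
#' @return The combined p-value.
#' @export
cauchy_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("cauchy_combine needs at least one p-value")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(pvalues, 1e-15), 1 - 1e-15)
  T <- mean(tan((0.5 - p) * pi))
  0.5 - atan(T) / pi
}

#' Bonferroni adjustment over tested TSS
#'
#' @param pvalues Combined p-values, one per tested TSS.
#' @param n Number of tests (default `length(pvalues)`).
#' @return `pmin(1, pvalues * n)`.
#' @export
bonferroni_adjust <- function(pvalues, n = length(pvalues)) {
  stopifnot(n >= 1)
  pmin(1, pvalues * n)
}

#' Differential TSS testing between two conditions
#'
#' For every TSS enriched in at least one of the two conditions, the enriched
#' coverage profiles around the TSS are compared between all replicate pairs
#' by KS tests ([pairwise_ks()]), combined per TSS with the Cauchy
#' combination test, and Bonferroni-corrected over all tested TSS. A TSS
#' whose windows are degenerate (no coverage) in one of the conditions is
#' skipped with a warning.
#'
#' @param tss A `tss_set`.
#' @param pairs Normalized [library_pair] list.
#' @param condition_a,condition_b Condition names to compare.
#' @param half_window Window half width in bp (default 50).
#' @return A data.frame with one row per tested TSS: `tss_id`, `replicon_id`,
#'   `position`, `strand`, `condition_a`, `condition_b`, `n_tests`,
#'   `ks_pvalues` (comma-joined), `combined_p`, `adjusted_p`; sorted by
#'   `adjusted_p`.
#' @export
differential_tss <- function(tss, pairs, condition_a, condition_b,
                             half_window = 50L) {
  stopifnot(inherits(tss, "tss_set"))
  for (cn in c(condition_a, condition_b))
    if (!cn %in% tss$condition_names)
      stop(sprintf("unknown condition '%s'; valid conditions: %s", cn,
                   paste(tss$condition_names, collapse = ", ")))
  enr <- tss$conditions[tss$conditions$enriched &
                          tss$conditions$condition %in%
                            c(condition_a, condition_b), , drop = FALSE]
  test_ids <- unique(enr$tss_id)
  if (length(test_ids) == 0L)
    return(data.frame(tss_id = integer(), replicon_id = character(),
                      position = integer(), strand = character(),
                      condition_a = character(), condition_b = character(),
                      n_tests = integer(), ks_pvalues = character(),
                      combined_p = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE))
  prof <- extract_profiles(tss, pairs, half_window,
                           conditions = c(condition_a, condition_b))
  rows <- list()
  for (id in test_ids) {
    w <- prof[[as.character(id)]]
    wa <- w[[condition_a]]; wb <- w[[condition_b]]
    ps <- if (length(wa) && length(wb))
      suppressWarnings(pairwise_ks(wa, wb)) else numeric(0)
    if (length(ps) == 0L) {
      warning(sprintf("TSS %d skipped: no valid profile pair between %s and %s",
                      id, condition_a, condition_b))
      next
    }
    k <- match(id, tss$tss$tss_id)
    rows[[length(rows) + 1L]] <- data.frame(
      tss_id = id, replicon_id = tss$tss$replicon_id[k],
      position = tss$tss$position[k], strand = tss$tss$strand[k],
      condition_a = condition_a, condition_b = condition_b,
      n_tests = length(ps),
      ks_pvalues = paste(sprintf("%.6g", ps), collapse = ","),
      combined_p = cauchy_combine(ps), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no TSS could be tested")
  out$adjusted_p <- bonferroni_adjust(out$combined_p, nrow(out))
  out <- out[order(out$adjusted_p, out$combined_p, out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
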