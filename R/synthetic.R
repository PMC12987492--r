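#' Specification of a synthetic TSS experiment
#'
#' Describes a multi-condition, multi-replicate experiment with planted TSS
#' and known ground truth, from which [generate_experiment()] writes wiggle
#' and GFF3 files. The default layout mirrors a typical comparative setup:
#' one untreated condition plus three treatments, three replicates each, one
#' replicon, 20 planted TSS spanning all five classes.
#'
#' The coverage model: each planted TSS contributes, on its strand, a sharp
#' step of the planted height at its position followed by exponentially
#' decaying gene-body coverage (`height * exp(-decay * d)` over
#' `transcript_length` bases downstream); the control library carries the
#' same signal divided by the planted enrichment factor (no 5' step excess).
#' Replicate-specific scale factors multiply both libraries and emulate
#' sequencing-depth differences; sparse uniform background noise can be added
#' on top. This emulates what a full-read coverage profile of a 5'-enriched
#' protocol looks like around a TSS; it is not a read-level simulator.
#'
#' @param replicon_id,replicon_length Replicon name and length (bp).
#' @param conditions Condition names.
#' @param n_replicates Replicates per condition.
#' @param genes data.frame with `locus_tag`, `name`, `product`, `start`,
#'   `end`, `strand`.
#' @param tss data.frame of planted TSS with `position`, `strand`, `height`,
#'   `enrichment_factor`, `expected_class`, `locus_tag` (empty for orphans),
#'   `conditions` (comma-joined subset of condition names), and optional
#'   `shift_condition`/`shift_bp` planting a condition-specific positional
#'   shift (for differential-test fixtures).
#' @param scale_factors Per-replicate library scale factors (recycled).
#' @param decay Exponential decay rate of gene-body coverage per bp.
#' @param transcript_length Length of the decaying signal (bp).
#' @param noise_level Upper bound of the sparse uniform background noise
#'   (coverage units; 0 disables noise).
#' @param noise_density Fraction of positions receiving background noise.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(replicon_id = "chr",
                           replicon_length = 20000L,
                           conditions = c("control", "trtA", "trtB", "trtC"),
                           n_replicates = 3L,
                           genes = default_synthetic_genes(),
                           tss = default_synthetic_tss(conditions),
                           scale_factors = c(1, 1.5, 0.75),
                           decay = 0.006,
                           transcript_length = 500L,
                           noise_level = 0,
                           noise_density = 0.02,
                           seed = 1L) {
  if (!"shift_condition" %in% names(tss)) tss$shift_condition <- NA_character_
  if (!"shift_bp" %in% names(tss)) tss$shift_bp <- 0L
  spec <- structure(
    list(replicon_id = replicon_id,
         replicon_length = as.integer(replicon_length),
         conditions = conditions, n_replicates = as.integer(n_replicates),
         genes = genes, tss = tss,
         scale_factors = rep_len(scale_factors, n_replicates),
         decay = decay, transcript_length = as.integer(transcript_length),
         noise_level = noise_level, noise_density = noise_density,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

default_synthetic_genes <- function() {
  data.frame(
    locus_tag = sprintf("sg%04d", 1:8),
    name = paste0("gene", LETTERS[1:8]),
    product = paste("synthetic protein", LETTERS[1:8]),
    start = c(1000L, 3000L, 5000L, 7000L, 9000L, 11000L, 13000L, 15000L),
    end = c(1900L, 3800L, 5900L, 7900L, 9900L, 11900L, 13900L, 15900L),
    strand = c("+", "+", "-", "+", "-", "+", "-", "+"),
    stringsAsFactors = FALSE)
}

default_synthetic_tss <- function(conditions = c("control", "trtA", "trtB",
                                                 "trtC")) {
  all <- paste(conditions, collapse = ",")
  trt <- paste(setdiff(conditions, conditions[1]), collapse = ",")
  if (!nzchar(trt)) trt <- all  # single-condition layout: no treatment subset
  cond2 <- if (length(conditions) >= 2) conditions[2] else conditions[1]
  data.frame(
    position = c(940L, 800L, 1500L, 2950L, 3400L, 5950L, 5500L, 5200L,
                 6950L, 7600L, 10100L, 9300L, 10950L, 11100L, 11300L,
                 14100L, 13500L, 14900L, 17500L, 18200L),
    strand = c("+", "+", "-", "+", "+", "-", "-", "+", "+", "-", "-", "-",
               "+", "+", "-", "-", "+", "+", "+", "-"),
    height = c(120, 60, 90, 150, 150, 200, 110, 80, 130, 95, 170, 140,
               100, 160, 85, 180, 75, 220, 250, 300),
    enrichment_factor = rep(4, 20),
    expected_class = c("primary", "secondary", "antisense", "primary",
                       "internal", "primary", "internal", "antisense",
                       "primary", "antisense", "primary", "internal",
                       "primary", "internal", "antisense", "primary",
                       "antisense", "primary", "orphan", "orphan"),
    locus_tag = c("sg0001", "sg0001", "sg0001", "sg0002", "sg0002",
                  "sg0003", "sg0003", "sg0003", "sg0004", "sg0004",
                  "sg0005", "sg0005", "sg0006", "sg0006", "sg0006",
                  "sg0007", "sg0007", "sg0008", "", ""),
    conditions = c(all, all, all, all, trt, all, all, all, all, all, all,
                   cond2, all, all, all, all, all, all,
                   conditions[1], all),
    stringsAsFactors = FALSE)
}

validate_synthetic_spec <- function(spec) {
  tssdf <- spec$tss
  if (any(tssdf$position < 1L | tssdf$position > spec$replicon_length))
    stop("planted TSS position outside the replicon")
  if (any(!unlist(strsplit(tssdf$conditions, ",")) %in% spec$conditions))
    stop("planted TSS references an unknown condition")
  # check the expected classes against the classifier itself
  ts <- empty_tss_set(spec$conditions)
  ord <- order(tssdf$strand, tssdf$position, method = "radix")
  ts$tss <- data.frame(tss_id = seq_along(ord),
                       replicon_id = spec$replicon_id,
                       strand = tssdf$strand[ord],
                       position = tssdf$position[ord],
                       stringsAsFactors = FALSE)
  ts$conditions <- data.frame(
    tss_id = seq_along(ord), condition = spec$conditions[1],
    detected = TRUE, enriched = TRUE, position = tssdf$position[ord],
    det_count = 1L, step_height = tssdf$height[ord],
    step_factor = Inf, enrichment_factor = tssdf$enrichment_factor[ord],
    stringsAsFactors = FALSE)
  genes <- cbind(replicon_id = spec$replicon_id, spec$genes)
  cls <- classify_tss(ts, genes, tss_params())
  got <- vapply(seq_along(ord), function(k)
    paste(sort(unique(cls$classes$tss_class[cls$classes$tss_id == k])),
          collapse = ","), character(1))
  want <- tssdf$expected_class[ord]
  bad <- which(!mapply(function(g, w) w %in% strsplit(g, ",")[[1]],
                       got, want))
  if (length(bad))
    stop(sprintf(
      "planted TSS at %s disagree with gene geometry (expected %s, classifier says %s)",
      paste(tssdf$position[ord][bad], collapse = ", "),
      paste(want[bad], collapse = ", "),
      paste(got[bad], collapse = "; ")))
  invisible(spec)
}

# Add one TSS signal (step + exponential decay) to enriched/control vectors.
add_signal <- function(enr, ctl, pos, strand, height, ef, decay, tx_len) {
  d <- 0:(tx_len - 1L)
  idx <- if (strand == "+") pos + d else pos - d
  ok <- idx >= 1L & idx <= length(enr)
  idx <- idx[ok]; d <- d[ok]
  sig <- height * exp(-decay * d)
  enr[idx] <- enr[idx] + sig
  ctl[idx] <- ctl[idx] + sig / ef
  list(enr = enr, ctl = ctl)
}

#' Build the library pairs of a synthetic experiment in memory
#'
#' The same coverage model as [generate_experiment()], without touching the
#' disk: returns one [library_pair] per condition/replicate/strand. Useful
#' for property checks that do not exercise file I/O. For a given spec the
#' values are identical to what [generate_experiment()] writes.
#'
#' @param spec A [synthetic_spec].
#' @return A list of [library_pair] objects.
#' @export
synthetic_pairs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$replicon_length
  pairs <- list()
  for (ci in seq_along(spec$conditions)) {
    cn <- spec$conditions[ci]
    present <- vapply(strsplit(spec$tss$conditions, ","),
                      function(x) cn %in% x, logical(1))
    for (ri in seq_len(spec$n_replicates)) {
      rn <- sprintf("rep%d", ri)
      sf <- spec$scale_factors[ri]
      for (std in c("+", "-")) {
        enr <- numeric(L); ctl <- numeric(L)
        for (k in which(present & spec$tss$strand == std)) {
          pos <- spec$tss$position[k]
          if (!is.na(spec$tss$shift_condition[k]) &&
              spec$tss$shift_condition[k] == cn)
            pos <- pos + spec$tss$shift_bp[k]
          r <- add_signal(enr, ctl, pos, std, spec$tss$height[k],
                          spec$tss$enrichment_factor[k], spec$decay,
                          spec$transcript_length)
          enr <- r$enr; ctl <- r$ctl
        }
        enr <- enr * sf; ctl <- ctl * sf
        if (spec$noise_level > 0) {
          for (nm in c("enr", "ctl")) {
            hit <- stats::runif(L) < spec$noise_density
            noise <- stats::runif(sum(hit), 0, spec$noise_level) * sf
            if (nm == "enr") enr[hit] <- enr[hit] + noise
            else ctl[hit] <- ctl[hit] + noise
          }
        }
        pairs[[length(pairs) + 1L]] <- library_pair(
          cn, rn, coverage_track(spec$replicon_id, std, enr),
          coverage_track(spec$replicon_id, std, ctl))
      }
    }
  }
  pairs
}

#' Generate a synthetic experiment on disk
#'
#' Writes, for every condition/replicate/strand, an enriched and a control
#' wiggle file, plus a GFF3 of the planted genes and a TSV of the planted
#' truth. Two runs from the same spec produce byte-identical files.
#'
#' @param spec A [synthetic_spec].
#' @param dir Output directory (created if needed).
#' @return A list with `layout` ([experiment_layout]), `truth` (the planted
#'   TSS table), `annotation` (GFF3 path), `truth_path`, and `dir`.
#' @export
generate_experiment <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory %s", dir))
  pairs <- synthetic_pairs(spec)
  L <- spec$replicon_length
  files <- list()
  for (p in pairs) {
    for (lib in c("enriched", "control")) {
      fn <- file.path(dir, paste0(
        wiggle_track_name(p$condition, p$replicate, p$strand, lib), ".wig"))
      con <- file(fn, "w")
      write_track_block(p[[lib]], con)
      close(con)
      files[[length(files) + 1L]] <- data.frame(
        condition = p$condition, replicate = p$replicate,
        strand = p$strand, library = lib, path = fn,
        stringsAsFactors = FALSE)
    }
  }
  gff <- file.path(dir, "annotation.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", spec$replicon_id, L), con)
  g <- spec$genes
  writeLines(sprintf(
    "%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s;gene=%s;product=%s",
    spec$replicon_id, g$start, g$end, g$strand, g$locus_tag, g$locus_tag,
    g$name, g$product), con)
  close(con)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(spec$tss, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(layout = experiment_layout(do.call(rbind, files),
                                  conditions = spec$conditions),
       truth = spec$tss, annotation = gff, truth_path = truth_path,
       dir = dir)
}

#' Score predicted TSS against planted truth
#'
#' A planted TSS is *recovered* when a predicted TSS lies within `tolerance`
#' bp on the same strand; a predicted TSS is a *true positive* when it
#' recovers some planted TSS. Class accuracy is, over recovered TSS, the
#' fraction whose predicted class set contains the planted expected class.
#'
#' @param truth Planted TSS table (from [generate_experiment()]).
#' @param predicted A classified `tss_set`.
#' @param tolerance Matching tolerance in bp (default 0: exact).
#' @return A list with `recall`, `precision`, `class_accuracy`, `n_planted`,
#'   `n_predicted`.
#' @export
score_recovery <- function(truth, predicted, tolerance = 0L) {
  stopifnot(inherits(predicted, "tss_set"))
  pred <- predicted$tss
  matched_pred <- rep(FALSE, nrow(pred))
  recovered <- rep(FALSE, nrow(truth))
  class_ok <- rep(NA, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hits <- which(pred$strand == truth$strand[i] &
                    abs(pred$position - truth$position[i]) <= tolerance)
    if (length(hits) == 0L) next
    recovered[i] <- TRUE
    matched_pred[hits] <- TRUE
    best <- hits[which.min(abs(pred$position[hits] - truth$position[i]))]
    pcls <- predicted$classes$tss_class[
      predicted$classes$tss_id == pred$tss_id[best]]
    class_ok[i] <- truth$expected_class[i] %in% pcls
  }
  list(recall = mean(recovered),
       precision = if (nrow(pred)) mean(matched_pred) else NA_real_,
       class_accuracy = if (any(recovered))
         mean(class_ok[recovered]) else NA_real_,
       n_planted = nrow(truth), n_predicted = nrow(pred))
}
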