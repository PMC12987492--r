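#' Per-base coverage track
#'
#' A dense, 1-based vector of non-negative expression values for one replicon
#' and one strand. Positions absent from the source file are zero. This is the
#' elementary container the whole pipeline operates on: the enriched and the
#' non-enriched (control) library of a sample each contribute one track per
#' strand.
#'
#' @param replicon_id Replicon (chromosome/plasmid) identifier.
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param values Numeric vector of per-base expression values, index = 1-based
#'   genomic position. Must be non-negative.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(replicon_id, strand, values) {
  strand <- match.arg(strand, c("+", "-"))
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE))
    stop("coverage_track values must be non-negative")
  if (anyNA(values))
    stop("coverage_track values must not contain NA")
  structure(
    list(replicon_id = as.character(replicon_id), strand = strand,
         values = values, length = length(values)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s (%s), %d bp, %d non-zero, max %.4g\n",
              x$replicon_id, x$strand, x$length,
              sum(x$values > 0), if (x$length) max(x$values) else 0))
  invisible(x)
}

#' @export
length.coverage_track <- function(x) x$length

#' Matched enriched/control library pair
#'
#' One replicate of one condition contributes, per strand and replicon, a pair
#' of coverage tracks: the 5'-enriched library (TEX-treated, Cappable-seq
#' capped, ...) and its non-enriched counterpart. Detection runs on the
#' enriched track; the control track supplies the enrichment factor.
#'
#' @param condition Condition (experiment) name.
#' @param replicate Replicate label.
#' @param enriched,control [coverage_track] objects of identical replicon,
#'   strand and length.
#' @return An object of class `library_pair`.
#' @export
library_pair <- function(condition, replicate, enriched, control) {
  stopifnot(inherits(enriched, "coverage_track"),
            inherits(control, "coverage_track"))
  if (enriched$replicon_id != control$replicon_id ||
      enriched$strand != control$strand ||
      enriched$length != control$length)
    stop("enriched and control tracks must share replicon, strand and length")
  structure(
    list(condition = as.character(condition),
         replicate = as.character(replicate),
         replicon_id = enriched$replicon_id,
         strand = enriched$strand,
         enriched = enriched, control = control),
    class = "library_pair"
  )
}

#' @export
print.library_pair <- function(x, ...) {
  cat(sprintf("<library_pair> %s / %s, %s (%s), %d bp\n",
              x$condition, x$replicate, x$replicon_id, x$strand,
              x$enriched$length))
  invisible(x)
}

pair_id <- function(pair) {
  paste(pair$condition, pair$replicate, pair$strand, pair$replicon_id,
        sep = "/")
}

# Expression at the position immediately 5' of every position, in transcript
# orientation: on the forward strand that is i - 1, on the reverse strand
# i + 1 (transcription runs toward decreasing coordinates). Outside the track
# the previous value is 0.
previous_values <- function(values, strand) {
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (strand == "+") c(0, values[-n]) else c(values[-1], 0)
}

step_factor_from <- function(e, prev) {
  ifelse(prev > 0, e / prev, ifelse(e > 0, Inf, 1))
}

#' Step height and step factor at a position
#'
#' The two quantities a transcript 5' end leaves in an enriched coverage
#' profile: the height change `e(i) - e(prev)` and the factor of height change
#' `e(i) / e(prev)`, where `prev` is the neighbouring position 5' of `i` in
#' transcript orientation (`i - 1` on the forward strand, `i + 1` on the
#' reverse strand; 0 outside the track). A zero previous value with positive
#' `e(i)` yields a step factor of `Inf`; two zeros yield a factor of 1.
#'
#' @param track A [coverage_track].
#' @param i 1-based position (vectorised).
#' @return A list with numeric components `height` and `factor`.
#' @export
step_metrics <- function(track, i) {
  stopifnot(inherits(track, "coverage_track"))
  i <- as.integer(i)
  if (any(i < 1L | i > track$length))
    stop(sprintf("position out of bounds [1, %d]", track$length))
  e <- track$values[i]
  iprev <- if (track$strand == "+") i - 1L else i + 1L
  prev <- ifelse(iprev >= 1L & iprev <= track$length,
                 track$values[pmax(pmin(iprev, track$length), 1L)], 0)
  list(height = e - prev, factor = step_factor_from(e, prev))
}
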