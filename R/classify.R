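#' Classify consolidated TSS relative to annotated genes
#'
#' Each TSS is compared against every gene on its replicon and assigned one
#' classification per qualifying association; a TSS can therefore carry
#' several classes at once (e.g. primary for one gene and antisense for a
#' gene on the opposite strand). The five classes:
#'
#' * **primary / secondary** — same strand, 1..`utr_length` bp upstream of
#'   the gene's translation start (the start codon base itself excluded). Per
#'   gene, exactly one upstream TSS is primary: the one with the largest
#'   enriched step height (ties to the shortest 5' UTR), or the 5'-most one
#'   under `primary_rule = "first"`. All other upstream TSS of that gene are
#'   secondary.
#' * **internal** — same strand, within the annotated gene body (a TSS
#'   exactly at the translation start is internal, not primary).
#' * **antisense** — opposite strand, inside the gene or within
#'   `antisense_distance` bp of either gene boundary (boundary included).
#' * **orphan** — associated with no gene; an orphan TSS carries exactly this
#'   one classification.
#'
#' TSS strength for the primary decision is the maximum step height over the
#' conditions in which the TSS is enriched.
#'
#' @param tss A `tss_set` from [consolidate_tss()].
#' @param genes Gene table from [read_gff()].
#' @param params A [tss_params] (uses `utr_length`, `antisense_distance`,
#'   `primary_rule`).
#' @return The `tss_set` with its `classes` data.frame filled: one row per
#'   (TSS, classification) with `tss_class`, `locus_tag`, `gene_name`,
#'   `product`, `utr_length` (primary/secondary only), `gene_length` and
#'   `offset` (signed distance from the gene's translation start in gene
#'   orientation; `NA` for orphans).
#' @export
classify_tss <- function(tss, genes, params) {
  stopifnot(inherits(tss, "tss_set"), inherits(params, "tss_params"))
  n <- nrow(tss$tss)
  strength <- vapply(seq_len(n), function(i) {
    cc <- tss$conditions[tss$conditions$tss_id == tss$tss$tss_id[i] &
                           tss$conditions$enriched, , drop = FALSE]
    if (nrow(cc) == 0L) return(0)
    max(cc$step_height)
  }, numeric(1))

  assoc <- list()    # raw (tss, gene) associations
  add <- function(i, g, klass, utr, offs) {
    assoc[[length(assoc) + 1L]] <<- data.frame(
      tss_id = tss$tss$tss_id[i], gene_row = g, tss_class = klass,
      utr_length = utr, offset = offs, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    pos <- tss$tss$position[i]
    std <- tss$tss$strand[i]
    gi <- which(genes$replicon_id == tss$tss$replicon_id[i])
    for (g in gi) {
      gs <- genes$start[g]; ge <- genes$end[g]; gstd <- genes$strand[g]
      offs <- if (gstd == "+") pos - gs else ge - pos
      if (gstd == std) {
        if (pos >= gs && pos <= ge) {
          add(i, g, "internal", NA_integer_, offs)
        } else {
          d <- if (std == "+") gs - pos else pos - ge
          if (d >= 1 && d <= params$utr_length)
            add(i, g, "upstream", as.integer(d), offs)
        }
      } else {
        if (pos >= gs - params$antisense_distance &&
            pos <= ge + params$antisense_distance)
          add(i, g, "antisense", NA_integer_, offs)
      }
    }
  }
  assoc <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(tss_id = integer(), gene_row = integer(),
               tss_class = character(), utr_length = integer(),
               offset = integer(), stringsAsFactors = FALSE)

  # resolve upstream associations into primary/secondary, per gene
  up <- which(assoc$tss_class == "upstream")
  for (g in unique(assoc$gene_row[up])) {
    rows <- up[assoc$gene_row[up] == g]
    if (params$primary_rule == "strongest") {
      s <- strength[match(assoc$tss_id[rows], tss$tss$tss_id)]
      win <- rows[order(-s, assoc$utr_length[rows])[1]]
    } else {
      # "first" = the 5'-most signal, i.e. the farthest upstream (largest UTR)
      win <- rows[order(-assoc$utr_length[rows])[1]]
    }
    assoc$tss_class[rows] <- "secondary"
    assoc$tss_class[win] <- "primary"
  }

  cls <- data.frame(
    tss_id = assoc$tss_id,
    tss_class = assoc$tss_class,
    locus_tag = genes$locus_tag[assoc$gene_row],
    gene_name = genes$name[assoc$gene_row],
    product = genes$product[assoc$gene_row],
    utr_length = assoc$utr_length,
    gene_length = genes$end[assoc$gene_row] -
      genes$start[assoc$gene_row] + 1L,
    offset = assoc$offset, stringsAsFactors = FALSE)
  orphans <- setdiff(tss$tss$tss_id, cls$tss_id)
  if (length(orphans))
    cls <- rbind(cls, data.frame(
      tss_id = orphans, tss_class = "orphan", locus_tag = "",
      gene_name = "", product = "", utr_length = NA_integer_,
      gene_length = NA_integer_, offset = NA_integer_,
      stringsAsFactors = FALSE))
  cls <- cls[order(cls$tss_id, match(cls$tss_class,
                                     c("primary", "secondary", "internal",
                                       "antisense", "orphan")),
                   cls$locus_tag, method = "radix"), , drop = FALSE]
  rownames(cls) <- NULL
  tss$classes <- cls
  tss
}

#' Sequence upstream of a TSS
#'
#' Returns the `n` bases 5' of the TSS in transcript orientation — genomic
#' bases `pos-n .. pos-1` on the forward strand, and the reverse complement
#' of `pos+1 .. pos+n` on the reverse strand. The TSS base itself is
#' excluded; the window is truncated at replicon boundaries.
#'
#' @param position 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param replicon_id Replicon name, looked up in `genome`.
#' @param genome A named `Biostrings::DNAStringSet` (or object coercible to
#'   one, e.g. a named character vector of sequences).
#' @param n Number of bases (default 50).
#' @return A character scalar (possibly shorter than `n` near a boundary).
#' @export
upstream_sequence <- function(position, strand, replicon_id, genome,
                              n = 50L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (!replicon_id %in% names(genome))
    stop(sprintf("replicon '%s' not present in the genome", replicon_id))
  seq <- genome[[replicon_id]]
  L <- length(seq)
  if (position < 1L || position > L)
    stop(sprintf("position %d outside replicon '%s' (1..%d)",
                 position, replicon_id, L))
  if (strand == "+") {
    lo <- max(1L, position - n); hi <- position - 1L
    if (hi < lo) return("")
    as.character(Biostrings::subseq(seq, lo, hi))
  } else {
    lo <- position + 1L; hi <- min(L, position + n)
    if (hi < lo) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(seq, lo, hi)))
  }
}
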