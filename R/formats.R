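#' Experiment layout: conditions x replicates x strands x libraries
#'
#' Describes which coverage file belongs to which slot of the experiment.
#' Every (condition, replicate) needs exactly four files: forward/reverse
#' strand times enriched/control library.
#'
#' @param files A data.frame with columns `condition`, `replicate`, `strand`
#'   (`"+"`/`"-"`), `library` (`"enriched"`/`"control"`) and `path`.
#' @param conditions Optional character vector fixing the condition order;
#'   defaults to order of first appearance.
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(files, conditions = NULL) {
  need <- c("condition", "replicate", "strand", "library", "path")
  if (!is.data.frame(files) || !all(need %in% names(files)))
    stop("files must be a data.frame with columns ",
         paste(need, collapse = ", "))
  files <- as.data.frame(files)[need]
  files[] <- lapply(files, as.character)
  if (!all(files$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(files$library %in% c("enriched", "control")))
    stop("library must be 'enriched' or 'control'")
  key <- interaction(files$condition, files$replicate, drop = TRUE)
  for (k in levels(key)) {
    sub <- files[key == k, ]
    slots <- paste(sub$strand, sub$library)
    want <- c("+ enriched", "+ control", "- enriched", "- control")
    if (nrow(sub) != 4L || !setequal(slots, want) || anyDuplicated(slots))
      stop(sprintf(
        "condition/replicate '%s' must have exactly 4 files (2 strands x 2 libraries); got: %s",
        k, paste(slots, collapse = ", ")))
  }
  if (is.null(conditions)) conditions <- unique(files$condition)
  if (!setequal(conditions, unique(files$condition)))
    stop("conditions must match the condition names in files")
  structure(list(files = files, conditions = as.character(conditions)),
            class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  reps <- tapply(x$files$replicate, x$files$condition,
                 function(r) length(unique(r)))
  cat(sprintf("<experiment_layout> %d condition(s): %s\n",
              length(x$conditions),
              paste(sprintf("%s (%d reps)", x$conditions,
                            reps[x$conditions]), collapse = ", ")))
  invisible(x)
}

layout_replicates <- function(layout, condition) {
  unique(layout$files$replicate[layout$files$condition == condition])
}

# Scan a wiggle file for the first malformed declaration or data line so a
# parse failure can be reported with its line number.
diagnose_wiggle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (idx in seq_along(lines)) {
    ln <- trimws(lines[idx])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser"))
      next
    if (grepl("^variableStep", ln)) {
      if (!grepl("^variableStep\\s+chrom=\\S+(\\s+span=\\d+)?\\s*$", ln))
        stop(sprintf("%s: malformed variableStep declaration at line %d: '%s'",
                     path, idx, ln))
    } else if (grepl("^fixedStep", ln)) {
      ok <- grepl("chrom=\\S+", ln) && grepl("start=\\d+", ln)
      if (!ok)
        stop(sprintf("%s: malformed fixedStep declaration at line %d: '%s'",
                     path, idx, ln))
    } else if (!grepl("^-?[0-9.eE+-]+(\\s+-?[0-9.eE+-]+)?$", ln)) {
      stop(sprintf("%s: malformed data line at line %d: '%s'", path, idx, ln))
    }
  }
  invisible(TRUE)
}

# Densify a GRanges of scored intervals into one coverage_track per replicon.
granges_to_tracks <- function(gr, strand, expected_length, path) {
  if (length(gr) == 0L) return(list())
  negs <- any(S4Vectors::mcols(gr)$score < 0)
  if (negs) {
    message(sprintf("%s: negative values converted to absolute values", path))
    S4Vectors::mcols(gr)$score <- abs(S4Vectors::mcols(gr)$score)
  }
  out <- list()
  for (rep_id in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == rep_id]
    maxpos <- max(GenomicRanges::end(sub))
    len <- expected_track_length(expected_length, rep_id)
    if (!is.null(len)) {
      if (maxpos > len)
        stop(sprintf(
          "%s: position %d on replicon '%s' exceeds expected length %d",
          path, maxpos, rep_id, len))
    } else len <- maxpos
    vals <- numeric(len)
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    sc <- S4Vectors::mcols(sub)$score
    for (k in seq_along(sub)) vals[st[k]:en[k]] <- sc[k]
    out[[rep_id]] <- coverage_track(rep_id, strand, vals)
  }
  out
}

expected_track_length <- function(expected_length, rep_id) {
  if (is.null(expected_length)) return(NULL)
  if (!is.null(names(expected_length))) {
    if (!rep_id %in% names(expected_length)) return(NULL)
    return(as.integer(expected_length[[rep_id]]))
  }
  as.integer(expected_length[1])
}

#' Read a wiggle coverage file
#'
#' Accepts both `variableStep` and `fixedStep` blocks, multiple declaration
#' blocks per file (one [coverage_track] per replicon) and optional `track`
#' header lines (skipped). Negative values — a common export convention for
#' reverse-strand coverage — are converted to absolute values, with a single
#' message per file. Positions not listed in the file are zero.
#'
#' @param path Path to the wiggle file.
#' @param strand Strand to stamp on the resulting tracks (`"+"` or `"-"`); the
#'   wiggle format itself is strand-agnostic.
#' @param expected_length Optional replicon length (single value, or named
#'   vector keyed by replicon id). Tracks are padded with zeros to this length
#'   and a position beyond it is an error.
#' @return A named list of [coverage_track] objects, one per replicon.
#' @export
read_wiggle <- function(path, strand = "+", expected_length = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "wig")),
    error = function(e) {
      diagnose_wiggle(path)  # throws with a line number when it finds the culprit
      stop(sprintf("%s: wiggle parse error: %s", path, conditionMessage(e)))
    })
  if (is.list(gr) && !inherits(gr, "GRanges"))
    gr <- unlist(methods::as(gr, "GRangesList"))
  granges_to_tracks(gr, strand, expected_length, path)
}

#' Read a bedGraph coverage file
#'
#' Four-column bedGraph with 0-based half-open intervals; interval `[s, e)`
#' with value `v` fills 1-based positions `s+1 .. e`. Overlapping intervals on
#' one replicon are rejected as ambiguous. Negative values are stored as
#' absolute values, as for [read_wiggle()].
#'
#' @inheritParams read_wiggle
#' @return A named list of [coverage_track] objects, one per replicon. An
#'   empty file yields an empty list.
#' @export
read_bedgraph <- function(path, strand = "+", expected_length = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (file.size(path) == 0L ||
      all(grepl("^\\s*(#|track|browser|$)", readLines(path, warn = FALSE))))
    return(list())
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "bedGraph")),
    error = function(e)
      stop(sprintf("%s: bedGraph parse error: %s", path,
                   conditionMessage(e))))
  hits <- GenomicRanges::countOverlaps(gr, gr)
  if (any(hits > 1L)) {
    bad <- gr[which(hits > 1L)[1]]
    stop(sprintf(
      "%s: overlapping intervals on replicon '%s' near position %d (ambiguous value)",
      path, as.character(GenomicRanges::seqnames(bad)),
      GenomicRanges::start(bad)))
  }
  granges_to_tracks(gr, strand, expected_length, path)
}

#' Read coverage in wiggle or bedGraph format
#'
#' Dispatches on the file extension (`.wig` / `.wiggle` vs `.bedgraph` /
#' `.bg` / `.bedGraph`).
#'
#' @inheritParams read_wiggle
#' @export
read_coverage <- function(path, strand = "+", expected_length = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bedgraph", "bg", "bdg"))
    read_bedgraph(path, strand, expected_length)
  else
    read_wiggle(path, strand, expected_length)
}

#' Read gene records from a GFF3 annotation
#'
#' Retains rows of type `gene`; for replicons without any `gene` row, `CDS`
#' rows are used instead. The locus tag is taken from the `locus_tag`
#' attribute, falling back to `ID`; the gene name from `gene` or `Name`; the
#' product from the feature's own `product` attribute or, for gene rows, from
#' a child CDS resolvable through `Parent`.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `replicon_id`, `locus_tag`, `name`,
#'   `product`, `start`, `end`, `strand` (start <= end always; strand is
#'   encoded separately).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop(sprintf("%s: GFF3 parse error: %s", path,
                                conditionMessage(e))))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  getattr <- function(d, field) {
    if (!field %in% names(d)) return(rep(NA_character_, nrow(d)))
    v <- d[[field]]
    if (is.list(v)) v <- vapply(v, function(x)
      if (length(x)) as.character(x[[1]]) else NA_character_, character(1))
    as.character(v)
  }
  pick <- df[df$type == "gene", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  no_gene <- setdiff(unique(cds$seqnames), unique(pick$seqnames))
  if (length(no_gene))
    pick <- rbind(pick, cds[cds$seqnames %in% no_gene, , drop = FALSE])
  if (nrow(pick) == 0L)
    return(data.frame(replicon_id = character(), locus_tag = character(),
                      name = character(), product = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  locus <- getattr(pick, "locus_tag")
  ids <- getattr(pick, "ID")
  locus[is.na(locus)] <- ids[is.na(locus)]
  name <- getattr(pick, "gene")
  alt <- getattr(pick, "Name")
  name[is.na(name)] <- alt[is.na(name)]
  prod <- getattr(pick, "product")
  # resolve product from child CDS for annotation styles that attach it there
  if (any(is.na(prod)) && nrow(cds) > 0L && "Parent" %in% names(cds)) {
    parents <- vapply(cds$Parent, function(x)
      if (length(x)) as.character(x[[1]]) else NA_character_, character(1))
    cds_prod <- getattr(cds, "product")
    hit <- match(ids, parents)
    fill <- is.na(prod) & !is.na(hit)
    prod[fill] <- cds_prod[hit[fill]]
  }
  out <- data.frame(
    replicon_id = pick$seqnames,
    locus_tag = locus,
    name = ifelse(is.na(name), "", name),
    product = ifelse(is.na(prod), "", prod),
    start = pick$start, end = pick$end,
    strand = ifelse(pick$strand == "-", "-", "+"),
    stringsAsFactors = FALSE)
  out[order(out$replicon_id, out$start, method = "radix"), , drop = FALSE]
}

fmt_num2 <- function(x) {
  ifelse(is.na(x), "",
         ifelse(is.infinite(x), "Inf", sprintf("%.2f", x)))
}

#' Write the MasterTable
#'
#' One row per (TSS, condition, classification): a TSS carrying two classes in
#' a three-condition experiment contributes six rows. Numeric fields are
#' rendered with two decimals; undefined values are empty.
#'
#' Columns: `SuperPos`, `SuperStrand` (cluster-representative coordinates),
#' `mapCount` (conditions in which the TSS was detected), `detCount`
#' (replicates detecting it in this condition), `Condition`, `detected`,
#' `enriched` (0/1), `stepHeight`, `stepFactor`, `enrichmentFactor`, `Pos`,
#' `Strand` (condition-local coordinates), `Locus_tag`, `GeneName`, `Product`,
#' `Class`, `UTRlength`, `GeneLength`, `Sequence-50nt` (upstream sequence,
#' empty unless a genome is supplied).
#'
#' @param tss A `tss_set` as returned by [classify_tss()].
#' @param layout The [experiment_layout] (fixes the condition order).
#' @param path Output TSV path.
#' @param genome Optional named `DNAStringSet` (or single sequence) used to
#'   fill the upstream-sequence column.
#' @param upstream_n Upstream sequence length in bp (default 50).
#' @return Invisibly, the data.frame that was written.
#' @export
write_master_table <- function(tss, layout, path, genome = NULL,
                               upstream_n = 50L) {
  df <- master_table(tss, layout, genome = genome, upstream_n = upstream_n)
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    stop(sprintf("cannot write MasterTable to %s: %s",
                                 path, conditionMessage(e))))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Assemble the MasterTable as a data.frame
#'
#' @inheritParams write_master_table
#' @return A data.frame, one row per (TSS, condition, classification).
#' @export
master_table <- function(tss, layout, genome = NULL, upstream_n = 50L) {
  stopifnot(inherits(tss, "tss_set"))
  conditions <- if (inherits(layout, "experiment_layout"))
    layout$conditions else as.character(layout)
  cols <- c("SuperPos", "SuperStrand", "mapCount", "detCount", "Condition",
            "detected", "enriched", "stepHeight", "stepFactor",
            "enrichmentFactor", "Pos", "Strand", "Locus_tag", "GeneName",
            "Product", "Class", "UTRlength", "GeneLength", "Sequence-50nt")
  empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), check.names = FALSE)
  if (nrow(tss$tss) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(tss$tss))) {
    t1 <- tss$tss[i, ]
    cls <- tss$classes[tss$classes$tss_id == t1$tss_id, , drop = FALSE]
    if (nrow(cls) == 0L)
      cls <- data.frame(tss_class = "", locus_tag = "", gene_name = "",
                        product = "", utr_length = NA_integer_,
                        gene_length = NA_integer_, stringsAsFactors = FALSE)
    cond <- tss$conditions[tss$conditions$tss_id == t1$tss_id, , drop = FALSE]
    seq50 <- if (!is.null(genome))
      upstream_sequence(t1$position, t1$strand, t1$replicon_id, genome,
                        n = upstream_n) else ""
    map_count <- sum(cond$detected)
    for (cn in conditions) {
      cc <- cond[cond$condition == cn, , drop = FALSE]
      if (nrow(cc) == 0L)
        cc <- data.frame(detected = FALSE, enriched = FALSE,
                         position = t1$position, det_count = 0L,
                         step_height = NA_real_, step_factor = NA_real_,
                         enrichment_factor = NA_real_)
      for (j in seq_len(nrow(cls))) {
        rows[[length(rows) + 1L]] <- data.frame(
          SuperPos = t1$position, SuperStrand = t1$strand,
          mapCount = map_count, detCount = cc$det_count,
          Condition = cn,
          detected = as.integer(cc$detected),
          enriched = as.integer(cc$enriched),
          stepHeight = fmt_num2(cc$step_height),
          stepFactor = fmt_num2(cc$step_factor),
          enrichmentFactor = fmt_num2(cc$enrichment_factor),
          Pos = cc$position, Strand = t1$strand,
          Locus_tag = cls$locus_tag[j], GeneName = cls$gene_name[j],
          Product = cls$product[j], Class = cls$tss_class[j],
          UTRlength = ifelse(is.na(cls$utr_length[j]), "",
                             as.character(cls$utr_length[j])),
          GeneLength = ifelse(is.na(cls$gene_length[j]), "",
                              as.character(cls$gene_length[j])),
          `Sequence-50nt` = seq50,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write per-condition TSS predictions as GFF3
#'
#' One 1-bp feature of type `TSS` per TSS enriched in the given condition, at
#' its condition-local position, with the class list and associated locus
#' tags in the attribute column.
#'
#' @param tss A classified `tss_set`.
#' @param condition Condition name.
#' @param path Output path.
#' @export
write_gff_output <- function(tss, condition, path) {
  stopifnot(inherits(tss, "tss_set"))
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    stop(sprintf("cannot write GFF to %s: %s", path,
                                 conditionMessage(e))))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  cond <- tss$conditions
  sel <- cond[cond$condition == condition & cond$enriched, , drop = FALSE]
  if (nrow(sel) == 0L) return(invisible(NULL))
  ord <- order(sel$tss_id)
  for (k in ord) {
    t1 <- tss$tss[match(sel$tss_id[k], tss$tss$tss_id), ]
    cls <- tss$classes[tss$classes$tss_id == sel$tss_id[k], , drop = FALSE]
    classes <- paste(cls$tss_class, collapse = ",")
    loci <- paste(unique(cls$locus_tag[nzchar(cls$locus_tag)]),
                  collapse = ",")
    attrs <- sprintf("ID=TSS_%s_%d;tss_class=%s", condition, sel$tss_id[k],
                     classes)
    if (nzchar(loci)) attrs <- paste0(attrs, ";locus_tag=", loci)
    writeLines(sprintf("%s\ttsscall\tTSS\t%d\t%d\t%s\t%s\t.\t%s",
                       t1$replicon_id, sel$position[k], sel$position[k],
                       fmt_num2(sel$step_height[k]), t1$strand, attrs), con)
  }
  invisible(NULL)
}

wiggle_track_name <- function(condition, replicate, strand, library) {
  sprintf("%s_%s_%s_%s", condition, replicate,
          ifelse(strand == "+", "fw", "rv"), library)
}

write_track_block <- function(track, con) {
  writeLines(sprintf("variableStep chrom=%s", track$replicon_id), con)
  nz <- which(track$values != 0)
  if (length(nz))
    writeLines(sprintf("%d %.10g", nz, track$values[nz]), con)
  invisible(NULL)
}

#' Export normalized coverage tracks as wiggle files
#'
#' Writes one variableStep wiggle file per (condition, replicate, strand,
#' library), sparse (zero positions omitted), named
#' `<condition>_<replicate>_<fw|rv>_<enriched|control>.wig`. Files written
#' here round-trip through [read_wiggle()].
#'
#' @param pairs List of [library_pair] objects (possibly several replicons per
#'   slot; replicons of the same slot share one file).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_normalized_tracks <- function(pairs, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory %s", dir))
  slots <- split(pairs, vapply(pairs, function(p)
    paste(p$condition, p$replicate, p$strand, sep = "\r"), character(1)))
  paths <- character(0)
  for (slot in slots) {
    p1 <- slot[[1]]
    for (lib in c("enriched", "control")) {
      fn <- file.path(dir, paste0(
        wiggle_track_name(p1$condition, p1$replicate, p1$strand, lib),
        ".wig"))
      con <- file(fn, "w")
      writeLines(sprintf("track type=wiggle_0 name=\"%s\"",
                         wiggle_track_name(p1$condition, p1$replicate,
                                           p1$strand, lib)), con)
      for (p in slot) write_track_block(p[[lib]], con)
      close(con)
      paths <- c(paths, fn)
    }
  }
  invisible(paths)
}
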