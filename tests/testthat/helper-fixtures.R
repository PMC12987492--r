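# small builders used across the suite

make_track <- function(values, strand = "+", replicon = "c1") {
  coverage_track(replicon, strand, values)
}

make_pair <- function(enriched, control, condition = "A", replicate = "r1",
                      strand = "+", replicon = "c1") {
  library_pair(condition, replicate,
               make_track(enriched, strand, replicon),
               make_track(control, strand, replicon))
}

# a track with steps planted at given positions (step height = `heights`,
# decaying tail), on a zero background
planted_track <- function(len, positions, heights, strand = "+",
                          decay = 0.01, tail = 150) {
  v <- numeric(len)
  for (k in seq_along(positions)) {
    d <- 0:(tail - 1)
    idx <- if (strand == "+") positions[k] + d else positions[k] - d
    ok <- idx >= 1 & idx <= len
    v[idx[ok]] <- v[idx[ok]] + heights[k] * exp(-decay * d[ok])
  }
  v
}

# reduced synthetic spec (2 conditions x 2 replicates) for property tests
mini_spec <- function(seed = 1L, noise_level = 0, ...) {
  conds <- c("A", "B")
  synthetic_spec(conditions = conds, n_replicates = 2L,
                 tss = default_tss_for(conds),
                 scale_factors = c(1, 1.6),
                 noise_level = noise_level, seed = seed, ...)
}

# the default planted-TSS table rewritten for an arbitrary condition set
default_tss_for <- function(conds) {
  tss <- tsscall:::default_synthetic_tss(conds)
  tss
}

# construct a minimal classified-ready tss_set by hand
manual_tss_set <- function(df, conditions = "A", enriched_in = NULL) {
  # df: data.frame(position, strand, strength); enriched_in: list of
  # condition vectors per TSS (default: enriched in all)
  ts <- tsscall:::empty_tss_set(conditions)
  ord <- order(df$strand, df$position)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  ts$tss <- data.frame(tss_id = seq_len(n), replicon_id = "c1",
                       strand = df$strand, position = as.integer(df$position),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    enr <- if (is.null(enriched_in)) conditions else enriched_in[[ord[i]]]
    for (cn in conditions) {
      rows[[length(rows) + 1L]] <- data.frame(
        tss_id = i, condition = cn, detected = cn %in% enr,
        enriched = cn %in% enr, position = as.integer(df$position[i]),
        det_count = as.integer(cn %in% enr),
        step_height = df$strength[i], step_factor = Inf,
        enrichment_factor = 4, stringsAsFactors = FALSE)
    }
  }
  ts$conditions <- do.call(rbind, rows)
  ts
}
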