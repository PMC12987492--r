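# Brute-force reference implementations, written as plain nested loops and
# kept independent of the package internals. They re-derive, position by
# position, what the vectorised pipeline computes in bulk.

oracle_step <- function(values, i, strand) {
  L <- length(values)
  ip <- if (strand == "+") i - 1 else i + 1
  prev <- if (ip >= 1 && ip <= L) values[ip] else 0
  e <- values[i]
  f <- if (prev > 0) e / prev else if (e > 0) Inf else 1
  list(height = e - prev, factor = f)
}

oracle_detect <- function(values, strand, h_thr, f_thr) {
  out <- NULL
  for (i in seq_along(values)) {
    m <- oracle_step(values, i, strand)
    if (m$height >= h_thr && m$factor >= f_thr)
      out <- rbind(out, data.frame(position = i, height = m$height,
                                   factor = m$factor))
  }
  if (is.null(out)) data.frame(position = integer(), height = numeric(),
                               factor = numeric()) else out
}

oracle_window_reduce <- function(df, W, mode, strand) {
  if (nrow(df) <= 1 || W == 0) return(df)
  df <- df[order(df$position), , drop = FALSE]
  runs <- list(); cur <- 1
  for (i in seq_len(nrow(df))[-1]) {
    if (df$position[i] - df$position[i - 1] <= W) cur <- c(cur, i)
    else { runs[[length(runs) + 1]] <- cur; cur <- i }
  }
  runs[[length(runs) + 1]] <- cur
  keep <- integer(0)
  for (r in runs) {
    if (mode == "strongest") {
      best <- r[1]
      for (i in r) if (df$height[i] > df$height[best]) best <- i
      keep <- c(keep, best)
    } else {
      keep <- c(keep, if (strand == "+") r[1] else r[length(r)])
    }
  }
  df[sort(keep), , drop = FALSE]
}

# full per-condition reconciliation + enrichment + cross-condition clustering
# on single-replicon, single-strand instances
oracle_consolidate <- function(enr, ctl, strand, params) {
  # enr/ctl: nested lists [[condition]][[replicate]] of numeric vectors
  h_thr <- params$step_height; f_thr <- params$step_factor
  h_red <- max(h_thr - params$step_height_reduction, 0)
  f_red <- max(f_thr - params$step_factor_reduction, 1)
  dr <- params$cross_replicate_shift
  per_cond <- list()
  for (cn in names(enr)) {
    reps <- names(enr[[cn]])
    cands <- NULL
    for (r in reps) {
      d <- oracle_detect(enr[[cn]][[r]], strand, h_thr, f_thr)
      d <- oracle_window_reduce(d, params$window, params$reduction_mode,
                                strand)
      if (nrow(d)) cands <- rbind(cands, cbind(d, replicate = r))
    }
    found <- NULL
    if (!is.null(cands)) {
      cands <- cands[order(cands$position), , drop = FALSE]
      # chain clusters
      cl <- list(); cur <- 1
      for (i in seq_len(nrow(cands))[-1]) {
        if (cands$position[i] - cands$position[i - 1] <= dr)
          cur <- c(cur, i)
        else { cl[[length(cl) + 1]] <- cur; cur <- i }
      }
      cl[[length(cl) + 1]] <- cur
      for (members in cl) {
        mm <- cands[members, , drop = FALSE]
        best <- 1
        for (i in seq_len(nrow(mm)))
          if (mm$height[i] > mm$height[best]) best <- i
        rep_pos <- mm$position[best]
        dets <- mm[, c("replicate", "position", "height", "factor")]
        for (r in setdiff(reps, unique(mm$replicate))) {
          v <- enr[[cn]][[r]]
          cand <- NULL
          for (j in max(1, rep_pos - dr):min(length(v), rep_pos + dr)) {
            m <- oracle_step(v, j, strand)
            if (v[j] > 0 && m$height >= h_red && m$factor >= f_red)
              if (is.null(cand) || m$height > cand$height)
                cand <- data.frame(replicate = r, position = j,
                                   height = m$height, factor = m$factor)
          }
          if (!is.null(cand)) dets <- rbind(dets, cand)
        }
        if (length(unique(dets$replicate)) < params$min_replicates) next
        top <- 1
        for (i in seq_len(nrow(dets)))
          if (dets$height[i] > dets$height[top] ||
              (dets$height[i] == dets$height[top] &&
                 dets$position[i] < dets$position[top])) top <- i
        # max EF across replicates at the TSS position
        efs <- c()
        for (r in reps) {
          e <- enr[[cn]][[r]][dets$position[top]]
          n <- ctl[[cn]][[r]][dets$position[top]]
          ef <- if (n > 0) e / n else if (e > 0) Inf else NA
          efs <- c(efs, ef)
        }
        efs <- efs[!is.na(efs)]
        enriched <- length(efs) > 0 && max(efs) >= params$enrichment_factor
        found <- rbind(found, data.frame(
          condition = cn, position = dets$position[top],
          height = dets$height[top],
          det_count = length(unique(dets$replicate)),
          enriched = enriched))
      }
    }
    per_cond[[cn]] <- found
  }
  pooled <- do.call(rbind, per_cond)
  if (is.null(pooled)) return(NULL)
  enr_tss <- pooled[pooled$enriched, , drop = FALSE]
  if (nrow(enr_tss) == 0) return(NULL)
  enr_tss <- enr_tss[order(enr_tss$position), , drop = FALSE]
  shift <- params$cross_condition_shift
  cl <- list(); cur <- 1
  for (i in seq_len(nrow(enr_tss))[-1]) {
    if (enr_tss$position[i] - enr_tss$position[i - 1] <= shift)
      cur <- c(cur, i)
    else { cl[[length(cl) + 1]] <- cur; cur <- i }
  }
  cl[[length(cl) + 1]] <- cur
  out <- NULL
  for (members in cl) {
    mm <- enr_tss[members, , drop = FALSE]
    # same-condition duplicates: keep the stronger
    for (cn in unique(mm$condition)) {
      rows <- which(mm$condition == cn)
      if (length(rows) > 1) {
        best <- rows[1]
        for (i in rows) if (mm$height[i] > mm$height[best]) best <- i
        mm <- mm[-setdiff(rows, best), , drop = FALSE]
      }
    }
    best <- 1
    for (i in seq_len(nrow(mm)))
      if (mm$height[i] > mm$height[best] ||
          (mm$height[i] == mm$height[best] &&
             mm$position[i] < mm$position[best])) best <- i
    out <- rbind(out, data.frame(
      position = mm$position[best],
      conditions = paste(sort(mm$condition), collapse = ","),
      stringsAsFactors = FALSE))
  }
  out[order(out$position), , drop = FALSE]
}

# independent classifier: every (TSS, gene) pair, explicit rules
oracle_classify <- function(tss, genes, utr_len, anti_dist,
                            rule = "strongest") {
  # tss: data.frame(position, strand, strength); returns list of sorted
  # class-label vectors, one per TSS row
  n <- nrow(tss)
  classes <- replicate(n, character(0), simplify = FALSE)
  upstream <- list()  # per gene: data.frame(tss_row, d)
  for (i in seq_len(n)) {
    for (g in seq_len(nrow(genes))) {
      gs <- genes$start[g]; ge <- genes$end[g]
      if (genes$strand[g] == tss$strand[i]) {
        if (tss$position[i] >= gs && tss$position[i] <= ge) {
          classes[[i]] <- c(classes[[i]], "internal")
        } else {
          d <- if (tss$strand[i] == "+") gs - tss$position[i]
               else tss$position[i] - ge
          if (d >= 1 && d <= utr_len) {
            key <- as.character(g)
            upstream[[key]] <- rbind(upstream[[key]],
                                     data.frame(tss_row = i, d = d))
          }
        }
      } else {
        if (tss$position[i] >= gs - anti_dist &&
            tss$position[i] <= ge + anti_dist)
          classes[[i]] <- c(classes[[i]], "antisense")
      }
    }
  }
  for (key in names(upstream)) {
    u <- upstream[[key]]
    best <- 1
    for (i in seq_len(nrow(u))) {
      if (rule == "strongest") {
        si <- tss$strength[u$tss_row[i]]
        sb <- tss$strength[u$tss_row[best]]
        if (si > sb || (si == sb && u$d[i] < u$d[best])) best <- i
      } else if (u$d[i] > u$d[best]) best <- i
    }
    for (i in seq_len(nrow(u)))
      classes[[u$tss_row[i]]] <- c(classes[[u$tss_row[i]]],
                                   if (i == best) "primary" else "secondary")
  }
  lapply(classes, function(cl)
    if (length(cl) == 0) "orphan" else sort(unique(cl)))
}
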