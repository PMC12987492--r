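params_basic <- tss_params(step_height = 10, step_factor = 2,
                           enrichment_factor = 2,
                           step_height_reduction = 4,
                           step_factor_reduction = 0.5, window = 0)

test_that("a missed replicate is re-evaluated at reduced thresholds", {
  # rep1 carries a full-height step at 100; rep2 only reaches
  # step_height - reduction/2 = 8 there
  e1 <- numeric(200); e1[100:120] <- 50
  e2 <- numeric(200); e2[100:120] <- 8
  pairs <- list(make_pair(e1, e1 / 4, "A", "r1"),
                make_pair(e2, e2 / 4, "A", "r2"))
  cands <- detect_all(pairs, params_basic)
  expect_equal(unique(cands$replicate), "r1")
  rec <- reconcile_replicates(cands, pairs, params_basic)
  expect_equal(rec$det_count, 2L)
  expect_equal(rec$position, 100L)

  # with min_replicates = 2 and a replicate that fails even the reduced
  # threshold, the TSS is dropped
  p2 <- tss_params(step_height = 10, step_factor = 2,
                   step_height_reduction = 4, window = 0,
                   min_replicates = 2)
  e3 <- numeric(200); e3[100:120] <- 2   # below 10 - 4
  pairs2 <- list(make_pair(e1, e1 / 4, "A", "r1"),
                 make_pair(e3, e3 / 4, "A", "r2"))
  rec2 <- reconcile_replicates(detect_all(pairs2, p2), pairs2, p2)
  expect_equal(nrow(rec2), 0L)
})

test_that("detections one bp apart across replicates are one TSS", {
  e1 <- numeric(200); e1[100:130] <- 40
  e2 <- numeric(200); e2[101:130] <- 40
  pairs <- list(make_pair(e1, e1 / 4, "A", "r1"),
                make_pair(e2, e2 / 4, "A", "r2"))
  rec <- reconcile_replicates(detect_all(pairs, params_basic), pairs,
                              params_basic)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$det_count, 2L)
})

test_that("min_replicates above the replicate count is a configuration error", {
  p <- tss_params(min_replicates = 3)
  pairs <- list(make_pair(numeric(10) + 1, numeric(10) + 1, "A", "r1"))
  expect_error(reconcile_replicates(tsscall:::empty_candidates(), pairs, p),
               "min_replicates")
})

test_that("enrichment semantics: double expression passes exactly at threshold 2", {
  det <- data.frame(replicon_id = "c1", strand = "+", position = 5L,
                    condition = "A", det_count = 1L, step_height = 10,
                    step_factor = Inf, stringsAsFactors = FALSE)
  mk <- function(e_val, n_val) {
    e <- numeric(10); e[5] <- e_val
    n <- numeric(10); n[5] <- n_val
    list(make_pair(e, n, "A", "r1"))
  }
  p <- tss_params(enrichment_factor = 2)
  # e_enr = 2 * e_non -> EF exactly 2, enriched
  out <- enrichment_filter(det, mk(10, 5), p)
  expect_equal(nrow(out), 1L)
  expect_equal(out$enrichment_factor, 2)
  # control zero -> EF infinite, enriched at any threshold
  out2 <- enrichment_filter(det, mk(10, 0),
                            tss_params(enrichment_factor = 100))
  expect_equal(out2$enrichment_factor, Inf)
  # just below the threshold -> dropped
  expect_equal(nrow(enrichment_filter(det, mk(10, 6), p)), 0L)
})

test_that("the maximal EF across replicates decides enrichment", {
  det <- data.frame(replicon_id = "c1", strand = "+", position = 5L,
                    condition = "A", det_count = 2L, step_height = 10,
                    step_factor = Inf, stringsAsFactors = FALSE)
  e <- numeric(10); e[5] <- 10
  n1 <- numeric(10); n1[5] <- 10 / 1.2
  n2 <- numeric(10); n2[5] <- 10 / 1.5
  pairs <- list(make_pair(e, n1, "A", "r1"), make_pair(e, n2, "A", "r2"))
  expect_equal(nrow(enrichment_filter(det, pairs,
                                      tss_params(enrichment_factor = 2))),
               0L)
  out <- enrichment_filter(det, pairs, tss_params(enrichment_factor = 1.4))
  expect_equal(out$enrichment_factor, 1.5)
})

test_that("cross-condition clustering merges within the shift and keeps the strongest", {
  enr <- data.frame(
    replicon_id = "c1", strand = "+", position = c(1000L, 1002L),
    condition = c("A", "B"), det_count = 1L,
    step_height = c(50, 80), step_factor = Inf,
    enrichment_factor = 4, enriched = TRUE, stringsAsFactors = FALSE)
  ts3 <- cluster_across_conditions(enr, tss_params(cross_condition_shift = 3))
  expect_equal(nrow(ts3$tss), 1L)
  expect_equal(ts3$tss$position, 1002L)  # strongest contributor
  expect_equal(sort(ts3$conditions$condition), c("A", "B"))
  expect_true(all(ts3$conditions$enriched))
  ts1 <- cluster_across_conditions(enr, tss_params(cross_condition_shift = 1))
  expect_equal(nrow(ts1$tss), 2L)
  # absent condition records are explicit
  expect_equal(sum(ts1$conditions$detected), 2L)
  expect_equal(nrow(ts1$conditions), 4L)
})

test_that("single condition, single replicate: consolidation is the identity", {
  e <- planted_track(500, c(50, 200, 380), c(40, 80, 60))
  pairs <- list(make_pair(e, e / 4, "A", "r1"))
  p <- tss_params(step_height = 10, step_factor = 2, window = 0)
  cands <- detect_all(pairs, p)
  direct <- enrichment_filter(
    data.frame(replicon_id = cands$replicon_id, strand = cands$strand,
               position = cands$position, condition = cands$condition,
               det_count = 1L, step_height = cands$step_height,
               step_factor = cands$step_factor, stringsAsFactors = FALSE),
    pairs, p)
  full <- consolidate_tss(cands, pairs, p)
  expect_equal(full$tss$position, direct$position)
  expect_equal(full$conditions$step_height, direct$step_height)
  expect_equal(full$conditions$enrichment_factor, direct$enrichment_factor)
})

test_that("consolidation matches brute-force enumeration on random instances", {
  set.seed(101)
  n_equal <- 0
  for (inst in 1:50) {
    L <- sample(80:200, 1)
    strand <- sample(c("+", "-"), 1)
    conds <- c("A", "B")
    reps <- c("r1", "r2")
    enr <- list(); ctl <- list(); pairs <- list()
    for (cn in conds) for (r in reps) {
      v <- numeric(L)
      steps <- sample(L, sample(3:8, 1))
      v[steps] <- runif(length(steps), 1, 12)
      # smear some signal downstream to create nontrivial factors
      for (s in steps[v[steps] > 6]) {
        idx <- s:min(L, s + 5)
        v[idx] <- pmax(v[idx], v[s] * 0.6)
      }
      w <- v / sample(c(1.2, 2, 4), 1)
      w[sample(L, 5)] <- runif(5, 0, 3)
      enr[[cn]][[r]] <- v; ctl[[cn]][[r]] <- w
      pairs[[length(pairs) + 1L]] <- make_pair(v, w, cn, r, strand)
    }
    params <- tss_params(step_height = 3, step_factor = 2,
                         enrichment_factor = 2,
                         step_height_reduction = 1,
                         step_factor_reduction = 0.5,
                         window = sample(0:3, 1),
                         cross_replicate_shift = 1L,
                         cross_condition_shift = sample(1:2, 1),
                         min_replicates = sample(1:2, 1))
    got <- suppressWarnings(
      consolidate_tss(detect_all(pairs, params), pairs, params,
                      conditions = conds))
    want <- oracle_consolidate(enr, ctl, strand, params)
    if (is.null(want)) {
      expect_equal(nrow(got$tss), 0L)
    } else {
      expect_equal(got$tss$position, want$position)
      got_conds <- vapply(got$tss$tss_id, function(id) {
        cc <- got$conditions
        paste(sort(cc$condition[cc$tss_id == id & cc$enriched]),
              collapse = ",")
      }, character(1))
      expect_equal(got_conds, want$conditions)
    }
    n_equal <- n_equal + 1
  }
  expect_equal(n_equal, 50L)
})

test_that("enriched TSS counts are monotone in the thresholds", {
  count_tss <- function(pairs, params, scale) {
    nrow(consolidate_tss(detect_all(pairs, params, scale), pairs, params,
                         scale)$tss)
  }
  for (seed in 1:5) {
    spec <- mini_spec(seed = seed, noise_level = 3)
    pairs <- normalize_experiment(synthetic_pairs(spec))
    scale <- pairs$stats$q_min
    pairs <- pairs$pairs
    base <- tss_params(step_height = 0.3, step_factor = 2,
                       enrichment_factor = 2, step_height_reduction = 0.2,
                       step_factor_reduction = 0.5)
    n0 <- count_tss(pairs, base, scale)
    for (knob in list(list(step_height = 1.0),
                      list(step_factor = 3.5),
                      list(enrichment_factor = 3.5),
                      list(min_replicates = 2L))) {
      pp <- base
      pp[names(knob)] <- knob
      expect_lte(count_tss(pairs, pp, scale), n0)
    }
  }
})
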