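genes1 <- data.frame(
  replicon_id = "c1",
  locus_tag = c("b1", "b2"), name = c("geneA", "geneB"),
  product = c("prodA", "prodB"),
  start = c(1000L, 1200L), end = c(2000L, 1600L),
  strand = c("+", "-"), stringsAsFactors = FALSE)

# the class *set* of a TSS (one classification row exists per associated
# gene, so labels can repeat across genes)
classes_of <- function(ts, id) {
  sort(unique(ts$classes$tss_class[ts$classes$tss_id == id]))
}

test_that("the five classes follow the gene-relative rules", {
  ts <- manual_tss_set(data.frame(
    position = c(900, 1500, 5000, 1700),
    strand = c("+", "+", "+", "-"),
    strength = c(10, 10, 10, 10)))
  ts <- classify_tss(ts, genes1, tss_params())
  ids <- ts$tss$tss_id[match(c(900, 1500, 5000, 1700),
                             ts$tss$position)]
  # 100 bp upstream of geneA -> primary with UTR 100
  expect_equal(classes_of(ts, ids[1]), "primary")
  cl1 <- ts$classes[ts$classes$tss_id == ids[1], ]
  expect_equal(cl1$utr_length, 100L)
  expect_equal(cl1$locus_tag, "b1")
  # inside geneA on its strand, inside geneB on the opposite one
  expect_equal(classes_of(ts, ids[2]), c("antisense", "internal"))
  # far from every gene -> orphan, and orphan is exclusive
  expect_equal(classes_of(ts, ids[3]), "orphan")
  # reverse-strand TSS inside geneA -> antisense to geneA; 100 bp
  # upstream of geneB's translation start (its end) -> primary of geneB
  expect_equal(classes_of(ts, ids[4]), c("antisense", "primary"))
})

test_that("one primary per gene: strongest wins, ties break to shortest UTR", {
  # heights 20 at UTR 250 and 80 at UTR 40 -> the stronger is primary
  ts <- manual_tss_set(data.frame(
    position = c(750, 960), strand = "+", strength = c(20, 80)))
  ts <- classify_tss(ts, genes1, tss_params())
  expect_equal(classes_of(ts, ts$tss$tss_id[ts$tss$position == 960]),
               "primary")
  expect_equal(classes_of(ts, ts$tss$tss_id[ts$tss$position == 750]),
               "secondary")
  # equal heights at UTR 100 and 200 -> shortest UTR is primary
  ts2 <- manual_tss_set(data.frame(
    position = c(800, 900), strand = "+", strength = c(50, 50)))
  ts2 <- classify_tss(ts2, genes1, tss_params())
  expect_equal(classes_of(ts2, ts2$tss$tss_id[ts2$tss$position == 900]),
               "primary")
  # a single upstream TSS is primary
  ts3 <- manual_tss_set(data.frame(position = 995, strand = "+",
                                   strength = 1))
  ts3 <- classify_tss(ts3, genes1, tss_params())
  expect_equal(classes_of(ts3, 1L), "primary")
  # under the "first" rule the 5'-most upstream TSS wins instead
  ts4 <- manual_tss_set(data.frame(
    position = c(750, 960), strand = "+", strength = c(20, 80)))
  ts4 <- classify_tss(ts4, genes1, tss_params(primary_rule = "first"))
  expect_equal(classes_of(ts4, ts4$tss$tss_id[ts4$tss$position == 750]),
               "primary")
})

test_that("a TSS at the translation start is internal, not primary", {
  ts <- manual_tss_set(data.frame(position = 1000, strand = "+",
                                  strength = 5))
  ts <- classify_tss(ts, genes1, tss_params())
  expect_equal(classes_of(ts, 1L), "internal")
})

test_that("antisense reaches exactly antisense_distance beyond the gene", {
  g <- genes1[1, ]  # + gene [1000, 2000]
  p <- tss_params(antisense_distance = 150)
  at <- function(pos) {
    ts <- manual_tss_set(data.frame(position = pos, strand = "-",
                                    strength = 1))
    classes_of(classify_tss(ts, g, p), 1L)
  }
  expect_equal(at(2150), "antisense")   # boundary included
  expect_equal(at(2151), "orphan")
  expect_equal(at(850), "antisense")
})

test_that("classification matches the brute-force oracle on random instances", {
  set.seed(77)
  for (inst in 1:25) {
    n_genes <- sample(3:20, 1)
    starts <- sample(100:1800, n_genes)
    genes <- data.frame(
      replicon_id = "c1",
      locus_tag = sprintf("g%03d", seq_len(n_genes)),
      name = "", product = "",
      start = starts, end = pmin(starts + sample(50:400, n_genes,
                                                 replace = TRUE), 2000L),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    n_tss <- sample(5:60, 1)
    tssdf <- data.frame(
      position = sample(1:2000, n_tss),
      strand = sample(c("+", "-"), n_tss, replace = TRUE),
      strength = round(runif(n_tss, 1, 100), 1))
    ts <- manual_tss_set(tssdf)
    ts <- classify_tss(ts, genes, tss_params())
    # oracle works on the set's (sorted) TSS table to share row identity
    want <- oracle_classify(
      data.frame(position = ts$tss$position, strand = ts$tss$strand,
                 strength = ts$conditions$step_height[
                   match(ts$tss$tss_id, ts$conditions$tss_id)]),
      genes, 300, 150)
    for (i in seq_len(nrow(ts$tss)))
      expect_equal(classes_of(ts, ts$tss$tss_id[i]), want[[i]])
  }
})

test_that("every TSS gets a class; orphan never co-occurs; one primary per gene", {
  set.seed(78)
  tssdf <- data.frame(position = sample(1:2500, 120),
                      strand = sample(c("+", "-"), 120, replace = TRUE),
                      strength = runif(120, 1, 50))
  ts <- classify_tss(manual_tss_set(tssdf), genes1, tss_params())
  expect_setequal(unique(ts$classes$tss_id), ts$tss$tss_id)
  for (id in unique(ts$classes$tss_id)) {
    cl <- classes_of(ts, id)
    if ("orphan" %in% cl) expect_equal(cl, "orphan")
  }
  prim <- ts$classes[ts$classes$tss_class == "primary", ]
  expect_false(anyDuplicated(prim$locus_tag) > 0)
})

test_that("upstream sequences are extracted in transcript orientation", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(
    rep(c("A", "C", "G", "T"), 25), collapse = "")))
  # forward: bases pos-n .. pos-1
  expect_equal(upstream_sequence(11, "+", "c1", genome, n = 4), "GTAC")
  # reverse: reverse complement of pos+1 .. pos+n
  expect_equal(upstream_sequence(11, "-", "c1", genome, n = 4), "CGTA")
  # truncation at the replicon start
  expect_equal(nchar(upstream_sequence(10, "+", "c1", genome, n = 50)), 9L)
  expect_error(upstream_sequence(5, "+", "nope", genome), "not present")
})
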