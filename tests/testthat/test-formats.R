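test_that("wiggle parsing handles variableStep, fixedStep and padding", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("track type=wiggle_0 name=demo",
               "variableStep chrom=c1", "3 5.0", "4 7.5"), f)
  tr <- read_wiggle(f, expected_length = 6)
  expect_named(tr, "c1")
  expect_equal(tr$c1$values, c(0, 0, 5.0, 7.5, 0, 0))

  f2 <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=c1 start=2 step=1", "1", "2"), f2)
  tr2 <- read_wiggle(f2)
  expect_equal(tr2$c1$values[2:3], c(1, 2))
  expect_equal(tr2$c1$values[1], 0)
})

test_that("negative coverage values are stored as absolute values", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=c1", "10 -3.5"), f)
  expect_message(tr <- read_wiggle(f), "absolute")
  expect_equal(tr$c1$values[10], 3.5)

  g <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("c1\t5\t6\t-1.0", g)
  expect_message(tb <- read_bedgraph(g), "absolute")
  expect_equal(tb$c1$values[6], 1.0)
})

test_that("positions beyond the expected length are a bounds error", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=c1", "10 2.0"), f)
  expect_error(read_wiggle(f, expected_length = 5), "exceeds expected length")
})

test_that("malformed wiggle declarations are reported with a line number", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=c1", "3 5.0",
               "variableStep notachrom"), f)
  expect_error(read_wiggle(f), "line 3")
})

test_that("bedGraph intervals convert 0-based half-open to 1-based", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("c1\t0\t3\t2.0", f)
  tr <- read_bedgraph(f)
  expect_equal(tr$c1$values, c(2, 2, 2))

  empty <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(character(0), empty)
  expect_identical(read_bedgraph(empty), list())

  overl <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("c1\t0\t5\t1.0", "c1\t3\t8\t2.0"), overl)
  expect_error(read_bedgraph(overl), "overlapping")
})

test_that("wiggle and bedGraph encodings of one profile load identically", {
  set.seed(42)
  vals <- numeric(50)
  nz <- sort(sample(50, 12))
  vals[nz] <- round(runif(12, 0.5, 20), 3)
  fw <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=c9", sprintf("%d %.10g", nz, vals[nz])),
             fw)
  fb <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(sprintf("c9\t%d\t%d\t%.10g", nz - 1L, nz, vals[nz]), fb)
  tw <- read_wiggle(fw)$c9
  tb <- read_bedgraph(fb)$c9
  expect_equal(tw$values, tb$values)
  expect_equal(tw$replicon_id, tb$replicon_id)
})

test_that("GFF3 gene records are extracted with attribute fallbacks", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\t.\tgene\t100\t400\t.\t+\t.\tID=g1;locus_tag=b0001;gene=thrL",
    "c1\t.\tgene\t600\t900\t.\t-\t.\tID=g2",
    "c1\t.\tCDS\t100\t400\t.\t+\t.\tID=c1cds;Parent=g1;product=thr operon leader peptide",
    "c2\t.\tCDS\t10\t90\t.\t+\t.\tID=cds7;locus_tag=b9999;product=hypothetical protein"),
    f)
  g <- read_gff(f)
  expect_equal(nrow(g), 3L)
  g1 <- g[g$locus_tag == "b0001", ]
  expect_equal(g1$name, "thrL")
  expect_equal(g1$start, 100L)
  expect_equal(g1$strand, "+")
  expect_equal(g1$product, "thr operon leader peptide")
  # gene without locus_tag falls back to ID
  expect_true("g2" %in% g$locus_tag)
  # replicon with only CDS rows uses them
  expect_true("b9999" %in% g$locus_tag[g$replicon_id == "c2"])
})

test_that("MasterTable has one row per TSS x condition x classification", {
  conds <- c("A", "B", "C")
  ts <- manual_tss_set(
    data.frame(position = 500, strand = "+", strength = 50), conds)
  ts$classes <- data.frame(
    tss_id = c(1L, 1L), tss_class = c("primary", "antisense"),
    locus_tag = c("b1", "b2"), gene_name = c("x", "y"),
    product = c("", ""), utr_length = c(60L, NA), gene_length = c(900L, 500L),
    offset = c(-60L, 10L), stringsAsFactors = FALSE)
  mt <- master_table(ts, conds)
  expect_equal(nrow(mt), 6L)  # 1 TSS x 3 conditions x 2 classes
  expect_setequal(unique(mt$Condition), conds)

  empty <- tsscall:::empty_tss_set(conds)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_master_table(empty, conds, f)
  expect_equal(length(readLines(f)), 1L)  # header only
})

test_that("MasterTable renders a reverse-strand primary TSS as in the field's tables", {
  ts <- manual_tss_set(
    data.frame(position = 2099734, strand = "-", strength = 316.07), "A")
  ts$classes <- data.frame(
    tss_id = 1L, tss_class = "primary", locus_tag = "b2028",
    gene_name = "ugd", product = "UDP-glucose 6-dehydrogenase",
    utr_length = 70L, gene_length = 1167L, offset = -70L,
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  mt <- write_master_table(ts, "A", f)
  row <- readLines(f)[2]
  for (fld in c("2099734", "-", "316.07", "b2028", "ugd"))
    expect_match(row, fld, fixed = TRUE)
})

test_that("per-condition GFF output carries position, strand and classes", {
  ts <- manual_tss_set(
    data.frame(position = c(500, 900), strand = c("+", "+"),
               strength = c(10, 20)),
    conditions = c("A", "B"),
    enriched_in = list(c("A", "B"), "B"))
  ts$classes <- data.frame(
    tss_id = c(1L, 1L, 2L), tss_class = c("primary", "antisense", "orphan"),
    locus_tag = c("b0001", "b0002", ""), gene_name = c("", "", ""),
    product = c("", "", ""), utr_length = NA_integer_,
    gene_length = NA_integer_, offset = NA_integer_,
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff_output(ts, "A", f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(length(lines), 2L)  # only TSS 1 is enriched in A
  expect_match(lines[2], "\tTSS\t500\t500\t")
  expect_match(lines[2], "tss_class=primary,antisense")
  expect_match(lines[2], "locus_tag=b0001,b0002")

  # a condition with no enriched TSS yields a header-only file
  ts2 <- manual_tss_set(
    data.frame(position = 500, strand = "+", strength = 10),
    conditions = c("A", "B"), enriched_in = list("B"))
  write_gff_output(ts2, "A", f)
  expect_equal(length(readLines(f)), 1L)
})

test_that("normalized track export round-trips and enumerates all slots", {
  pairs <- list()
  set.seed(7)
  for (cn in c("A", "B")) for (rn in c("r1", "r2"))
    for (std in c("+", "-")) {
      v <- numeric(40); v[sample(40, 10)] <- runif(10, 0.1, 9)
      w <- numeric(40); w[sample(40, 10)] <- runif(10, 0.1, 9)
      pairs[[length(pairs) + 1L]] <-
        make_pair(v, w, cn, rn, std, "c1")
    }
  dir <- withr::local_tempdir()
  paths <- write_normalized_tracks(pairs, dir)
  expect_equal(length(paths), 16L)  # 2 cond x 2 rep x 2 strands x 2 libs
  # round trip within 1e-6; zeros omitted from the file
  p1 <- pairs[[1]]
  fn <- file.path(dir, "A_r1_fw_enriched.wig")
  expect_true(fn %in% paths)
  expect_false(any(grepl("^\\d+ 0$", readLines(fn))))
  back <- read_wiggle(fn, expected_length = 40)
  expect_equal(back$c1$values, p1$enriched$values, tolerance = 1e-6)
})
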