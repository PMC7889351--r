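mk_interaction_file <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(InteractorAChr = "chr1", InteractorAStart = c(1001, 5001, 9001),
             InteractorAEnd = c(2000, 6000, 10000),
             InteractorBChr = "chr1",
             InteractorBStart = c(30001, 40001, 50001),
             InteractorBEnd = c(31000, 41000, 52000),
             Agg_Gene_A = c("GENEA", "GENEB", "GENEA"), Agg_Gene_B = "",
             Detection_Method = "Hi-C", Cell_Tissue = "test",
             stringsAsFactors = FALSE)
}

test_that("interaction loading converts coordinates and skips bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  recs <- load_interactions(mk_interaction_file(base_rows(), path))
  expect_equal(nrow(recs), 3L)
  # 1-based inclusive -> 0-based half-open: start shifted by -1, end kept
  expect_equal(recs$InteractorAStart, c(1000, 5000, 9000))
  expect_equal(recs$InteractorAEnd, c(2000, 6000, 10000))
  expect_identical(attr(recs, "n_skipped"), 0L)

  bad <- base_rows()
  bad$InteractorBEnd[2] <- bad$InteractorBStart[2] - 5  # end <= start
  mk_interaction_file(bad, path)
  expect_warning(recs2 <- load_interactions(path), "skipped")
  expect_equal(nrow(recs2), 2L)
  expect_identical(attr(recs2, "n_skipped"), 1L)

  mk_interaction_file(base_rows()[, -7], path)
  expect_error(load_interactions(path), "Agg_Gene_A")

  # round trip through the on-disk convention
  out <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(recs, out)
  expect_equal(load_interactions(out), recs, ignore_attr = TRUE)
})

test_that("signed distances follow the strand-aware upstream=negative rule", {
  rec <- data.frame(InteractorAChr = "chr1", InteractorAStart = 300,
                    InteractorAEnd = 500, InteractorBChr = "chr2",
                    InteractorBStart = 0, InteractorBEnd = 10,
                    Agg_Gene_A = "G", Agg_Gene_B = "")
  plus <- data.frame(symbol = "G", chrom = "chr1", tss = 1000, strand = "+")
  minus <- data.frame(symbol = "G", chrom = "chr1", tss = 1000, strand = "-")
  # + strand, partner [300,500) -> midpoint 400 -> upstream 600 bp
  expect_equal(signed_distance(rec, plus, "A"), -600)
  # - strand: same locus is downstream in gene orientation
  expect_equal(signed_distance(rec, minus, "A"), 600)
  rec2 <- rec
  rec2$InteractorAStart <- 4000; rec2$InteractorAEnd <- 6000
  expect_equal(signed_distance(rec2, plus, "A"), 4000)
  # flip_sign covers the opposite reported convention
  expect_equal(signed_distance(rec, plus, "A", flip_sign = TRUE), 600)
  # strand-agnostic mode ignores orientation
  expect_equal(signed_distance(rec, minus, "A", strand_aware = FALSE), -600)
  # trans partner is the caller's responsibility
  expect_error(signed_distance(rec, plus, "B"), "trans")
})

test_that("distance sets pick the partner interactor and report coverage", {
  path <- withr::local_tempfile(fileext = ".tsv")
  recs <- load_interactions(mk_interaction_file(base_rows(), path))
  anchors <- data.frame(symbol = c("GENEA", "GENEB"), chrom = "chr1",
                        tss = c(1500, 5500), strand = c("+", "+"))
  ds <- distance_set(recs, c("GENEA", "GENEB", "GENEC"), anchors)
  # GENEA: two records; partner midpoints 30500 and 51000 relative to 1500
  expect_equal(sort(ds$per_gene$distance[ds$per_gene$gene == "GENEA"]),
               c(30500 - 1500, 51000 - 1500))
  expect_equal(ds$per_gene$distance[ds$per_gene$gene == "GENEB"],
               40500 - 5500)
  expect_identical(ds$missing_anchor, "GENEC")

  # both interactors naming the gene: partner = the one without the TSS
  both <- base_rows()[1, ]
  both$Agg_Gene_B <- "GENEA"
  recs2 <- load_interactions(mk_interaction_file(both, path))
  anc_in_a <- data.frame(symbol = "GENEA", chrom = "chr1", tss = 1500,
                         strand = "+")
  d2 <- distance_set(recs2, "GENEA", anc_in_a)
  expect_equal(d2$per_gene$distance, 30500 - 1500)
  # TSS in neither interactor: undecidable, dropped and counted
  anc_out <- data.frame(symbol = "GENEA", chrom = "chr1", tss = 99999,
                        strand = "+")
  d3 <- distance_set(recs2, "GENEA", anc_out)
  expect_length(d3$distances, 0L)
  expect_identical(d3$n_dropped, 1L)
})

test_that("generator-planted offsets are recovered exactly", {
  genes_up <- mk_symbols(10, "U"); genes_dn <- mk_symbols(10, "D")
  gi <- gen_interactions(41, genes_up, genes_dn, n_per_set = 30,
                         dir = withr::local_tempdir())
  recs <- suppressWarnings(load_interactions(gi$paths$interactions))
  anc <- read_anchors(gi$paths$anchors)
  up <- distance_set(recs, genes_up, anc, label = "up")
  dn <- distance_set(recs, genes_dn, anc, label = "down")
  expect_identical(sort(up$distances), sort(gi$truth$up$distance))
  expect_identical(sort(dn$distances), sort(gi$truth$down$distance))
  expect_identical(attr(recs, "n_skipped"), gi$truth$n_malformed)
  expect_identical(up$n_trans + dn$n_trans, gi$truth$n_trans)
  # degenerate distribution: all offsets at -1e4
  gi0 <- gen_interactions(42, genes_up, character(0), n_per_set = 5,
                          mag_range = c(1e4, 1e4), up_downstream_bias = 0,
                          n_trans = 0, n_malformed = 0)
  expect_true(all(gi0$truth$up$distance == -1e4))
})

test_that("KS comparison matches trivia, the sweep oracle and stats::ks.test", {
  expect_equal(ks_compare(1:10, 1:10)$statistic, 0)
  expect_equal(ks_compare(1:10, 1:10)$p_value, 1)
  expect_equal(ks_compare(1:10, 101:110)$statistic, 1)
  expect_error(ks_compare(numeric(0), 1:3), "non-empty")

  set.seed(55)
  for (i in 1:30) {
    a <- sample(1:40, sample(3:50, 1), replace = TRUE) + round(rnorm(1), 2)
    b <- rnorm(sample(3:50, 1), mean = runif(1, -1, 1))
    got <- ks_compare(a, b)
    expect_equal(got$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("reflection about the TSS negates distances but fixes D", {
  set.seed(77)
  a <- rnorm(40, 5); b <- rnorm(35, -2)
  expect_equal(ks_compare(-a, -b)$statistic, ks_compare(a, b)$statistic,
               tolerance = 1e-12)
})

test_that("ECDF tables are monotone from 0 to 1", {
  set.seed(88)
  tab <- ecdf_table(rnorm(100))
  expect_false(is.unsorted(tab$ecdf))
  expect_false(is.unsorted(tab$distance))
  expect_equal(tab$ecdf[nrow(tab)], 1)
  expect_gt(tab$ecdf[1], 0)
})
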