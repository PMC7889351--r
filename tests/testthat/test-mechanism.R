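mk_reference <- function(genes, id = "ref", direction = "up") {
  structure(list(dataset_id = id, direction = direction, genes = genes,
                 catalog_total = 1376L,
                 percent = percent_of_catalog(length(genes), 1376L)),
            class = "modulated_set")
}

test_that("concordance reproduces the checkpoint-overexpression figures", {
  ref <- mk_reference(mk_symbols(77, "R"))
  # perturbation moves 8 reference genes up, 1 down
  fc <- stats::setNames(c(rep(2, 8), -2, rep(1, 68)), ref$genes)
  cell <- concordance(ref, mk_contrast(fc, id = "b7h4"))
  expect_equal(cell$pct_up, 10.4)
  expect_equal(cell$pct_down, 1.3)
  expect_equal(cell$n_unchanged, 68L)
  expect_equal(cell$n_unmeasured, 0L)
})

test_that("self-concordance and unmeasured accounting are exact", {
  genes <- mk_symbols(30, "S")
  src <- mk_contrast(stats::setNames(rep(2, 30), genes), id = "src")
  deg <- call_degs(src, genes)
  ref <- modulated_set(deg, "up")
  self <- concordance(ref, src)
  expect_equal(self$pct_up, 100)
  expect_equal(self$n_up, 30L)

  # perturbation platform missing 10 reference genes
  part <- mk_contrast(stats::setNames(rep(2, 20), genes[1:20]), id = "part")
  cell <- concordance(ref, part)
  expect_equal(cell$n_unmeasured, 10L)
  expect_equal(cell$n_up + cell$n_down + cell$n_unchanged +
                 cell$n_unmeasured, cell$size)
  # default denominator is the full reference size
  expect_equal(cell$pct_up, percent_of_catalog(20, 30))
  # measured-denominator mode excludes them
  cellm <- concordance(ref, part, measured_denominator = TRUE)
  expect_equal(cellm$pct_up, 100)

  expect_error(concordance(mk_reference(character(0)), part), "empty")
})

test_that("binning equals exhaustive per-gene checks and is antisymmetric", {
  set.seed(23)
  genes <- mk_symbols(60, "G")
  ref <- mk_reference(genes)
  fc <- stats::setNames(sample(c(-1, 1), 60, TRUE) * runif(60, 1, 3), genes)
  pert <- mk_contrast(fc, id = "p1")
  cell <- concordance(ref, pert)
  expect_setequal(cell$genes_up, names(fc)[fc >= 1.5])
  expect_setequal(cell$genes_down, names(fc)[fc <= -1.5])
  # inverting the perturbation swaps the bins exactly
  inv <- mk_contrast(stats::setNames(-fc, genes), id = "p1inv")
  icell <- concordance(ref, inv)
  expect_identical(icell$genes_up, cell$genes_down)
  expect_identical(icell$genes_down, cell$genes_up)
  expect_equal(icell$n_unchanged, cell$n_unchanged)
})

test_that("the concordance matrix is a stable cross product", {
  refs <- list(mk_reference(mk_symbols(10, "A"), "r1"),
               mk_reference(mk_symbols(10, "B"), "r2", "down"))
  perts <- list(mk_contrast(stats::setNames(rep(2, 3), mk_symbols(10, "A")[1:3]),
                            id = "p1"),
                mk_contrast(stats::setNames(rep(-2, 2), mk_symbols(10, "B")[1:2]),
                            id = "p2"))
  cm <- concordance_matrix(refs, perts)
  expect_length(cm, 4L)
  df <- as.data.frame(cm)
  expect_equal(df$reference_id, c("r1", "r1", "r2", "r2"))
  # permuting perturbations reorders the same cells
  cm2 <- concordance_matrix(refs, rev(perts))
  df2 <- as.data.frame(cm2)
  key <- function(d) d[order(d$reference_id, d$perturbation_id), ]
  expect_equal(key(df), key(df2), ignore_attr = TRUE)
})

test_that("mechanism ranking uses union semantics and breaks ties by name", {
  genes <- mk_symbols(20, "M")
  ref <- mk_reference(genes)
  all_mover <- mk_contrast(stats::setNames(rep(2, 20), genes), id = "d_all")
  nothing <- mk_contrast(stats::setNames(rep(1, 20), genes), id = "d_none")
  cm <- concordance_matrix(list(ref), list(all_mover, nothing))
  rk <- rank_mechanisms(cm, c(d_all = "alpha", d_none = "beta"))
  expect_equal(rk$related_fraction, c(100, 0))
  expect_equal(rk$mechanism, c("alpha", "beta"))

  # duplicated dataset does not change the fraction (>=1 dataset semantics)
  cm_dup <- concordance_matrix(list(ref),
                               list(all_mover, {
                                 x <- all_mover; x$dataset_id <- "d_all2"; x
                               }))
  rk_dup <- rank_mechanisms(cm_dup, c(d_all = "alpha", d_all2 = "alpha"))
  expect_equal(rk_dup$related_fraction, 100)

  # equal plants tie, alphabetical order retained
  half1 <- mk_contrast(stats::setNames(c(rep(2, 10), rep(1, 10)), genes),
                       id = "h1")
  half2 <- mk_contrast(stats::setNames(c(rep(1, 10), rep(2, 10)), genes),
                       id = "h2")
  rk_tie <- rank_mechanisms(concordance_matrix(list(ref), list(half1, half2)),
                            c(h1 = "zeta", h2 = "eta"))
  expect_equal(rk_tie$related_fraction, c(50, 50))
  expect_equal(rk_tie$mechanism, c("eta", "zeta"))

  expect_error(rank_mechanisms(cm, c(d_all = "alpha")), "without a mechanism")
})

test_that("a planted suite recovers its mechanism ordering exactly", {
  catalog <- mk_symbols(400)
  sim <- gen_expression(101, catalog, n_up = 77, n_down = 39)
  deg <- call_degs(sim$contrast, catalog)
  ref <- modulated_set(deg, "up")
  suite <- gen_perturbation_suite(102, ref)
  cm <- concordance_matrix(list(ref), suite$contrasts)
  # zero noise: each cell equals its planted counts exactly
  for (cell in cm) {
    truth <- suite$truth[[cell$perturbation_id]]
    expect_identical(cell$genes_up, truth$up)
    expect_identical(cell$genes_down, truth$down)
    expect_equal(cell$pct_up,
                 percent_of_catalog(length(truth$up), cell$size))
  }
  rk <- rank_mechanisms(cm, suite$grouping)
  expect_equal(rk$mechanism, c("ros", "checkpoint", "cytokine", "shear_heat"))
})
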