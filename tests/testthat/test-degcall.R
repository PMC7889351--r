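test_that("signed fold change follows the magnitude >= 1 convention", {
  expect_equal(signed_fold_change(3, 2), 1.5)
  expect_equal(signed_fold_change(2, 3), -1.5)
  expect_equal(signed_fold_change(5, 5), 1)
  expect_error(signed_fold_change(0, 2), "positive")
  expect_error(signed_fold_change(2, -1), "positive")
  # sign symmetry under group swap, vectorized
  set.seed(7)
  a <- runif(50, 0.1, 100); b <- runif(50, 0.1, 100)
  unequal <- abs(a - b) > 1e-9
  expect_equal(signed_fold_change(a, b)[unequal],
               -signed_fold_change(b, a)[unequal])
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("probe collapse keeps max magnitude and flags sign ties", {
  rows <- data.frame(
    feature_id = paste0("p", 1:5),
    symbol = c("A", "A", "B", "B", "C"),
    treat_mean = 1, control_mean = 1,  # placeholders
    signed_fc = c(1.4, 1.8, 1.6, -1.6, -2.2))
  out <- collapse_probes(rows)
  expect_equal(out$rows$signed_fc[out$rows$symbol == "A"], 1.8)
  expect_identical(out$ambiguous, "B")
  expect_false("B" %in% out$rows$symbol)
  expect_equal(out$rows$signed_fc[out$rows$symbol == "C"], -2.2)
})

test_that("probe collapse equals an exhaustive per-gene scan (oracle)", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 300L
    rows <- data.frame(
      feature_id = paste0("p", seq_len(n)),
      symbol = sample(mk_symbols(60), n, replace = TRUE),
      treat_mean = 1, control_mean = 1,
      signed_fc = sample(c(-1, 1), n, TRUE) *
        round(runif(n, 1, 3), 1))
    got <- collapse_probes(rows)
    for (g in unique(rows$symbol)) {
      fc <- rows$signed_fc[rows$symbol == g]
      m <- max(abs(fc))
      tie <- any(fc == m) && any(fc == -m)
      if (tie) {
        expect_true(g %in% got$ambiguous)
      } else {
        expect_equal(got$rows$signed_fc[got$rows$symbol == g],
                     fc[which.max(abs(fc))])
      }
    }
  }
})

test_that("housekeeping QC reproduces the published pass and fails on breach", {
  # published fold changes for the second hyperthermia dataset
  ct <- mk_contrast(c(X1 = 2.0), housekeeping = TRUE,
                    hk_fc = c(1.160, 1.087, 1.128, 1.284))
  qc <- housekeeping_qc(ct)
  expect_true(qc$pass)
  expect_equal(qc$max_abs_fc, 1.284)
  expect_equal(unname(qc$values["GAPDH"]), 1.284, tolerance = 1e-9)
  expect_equal(unname(qc$values["CHMP2A"]), 1.160, tolerance = 1e-9)

  bad <- mk_contrast(c(X1 = 2.0), hk_fc = c(-1.6, 1.0, 1.0, 1.0))
  expect_false(housekeeping_qc(bad)$pass)

  # absent housekeeping gene fails with reason, not an exception
  noh <- suppressWarnings(as_contrast(
    data.frame(feature_id = "p1", symbol = "GAPDH",
               treat_mean = 100, control_mean = 100), "d1"))
  qc2 <- housekeeping_qc(noh)
  expect_false(qc2$pass)
  expect_setequal(qc2$missing, c("CHMP2A", "PSMB4", "ACTB"))
})

test_that("DEG calling includes the boundary and respects the catalog", {
  ct <- mk_contrast(c(A = 1.5, B = 1.49, C = -1.5, D = -3, E = 1.51))
  deg <- call_degs(ct, c("A", "B", "C", "D"))
  expect_setequal(deg$up, "A")          # boundary included, E not in catalog
  expect_setequal(deg$down, c("C", "D"))

  none <- call_degs(mk_contrast(c(A = 1.49, B = 1.49)), c("A", "B"))
  expect_length(none$up, 0L)
  expect_length(none$down, 0L)
})

test_that("QC failure blocks DEG calling unless overridden", {
  ct <- mk_contrast(c(A = 2), hk_fc = c(1.7, 1, 1, 1))
  err <- tryCatch(call_degs(ct, "A"), error = identity)
  expect_s3_class(err, "qc_failure")
  expect_s3_class(err$qc, "qc_report")
  expect_warning(deg <- call_degs(ct, "A", override_qc = TRUE), "overridden")
  expect_identical(deg$up, "A")
})

test_that("swapping treatment and control mirrors every call (property)", {
  set.seed(5)
  sym <- mk_symbols(80)
  treat <- runif(80, 10, 1000); control <- runif(80, 10, 1000)
  mk <- function(t, c) {
    with_qc(as_contrast(data.frame(feature_id = paste0(sym, "_p"),
                                   symbol = sym, treat_mean = t,
                                   control_mean = c), "d"))
  }
  fwd <- mk(treat, control); rev <- mk(control, treat)
  expect_equal(fwd$rows$signed_fc, -rev$rows$signed_fc)
  dfwd <- call_degs(fwd, sym, override_qc = TRUE) |> suppressWarnings()
  drev <- call_degs(rev, sym, override_qc = TRUE) |> suppressWarnings()
  expect_identical(dfwd$up, drev$down)
  expect_identical(dfwd$down, drev$up)
})

test_that("raising the threshold never adds DEGs (property)", {
  sim <- gen_expression(17, mk_symbols(400), n_up = 40, n_down = 40,
                        effect_fc = 2, noise_sd = 0.3)
  prev_up <- NULL; prev_down <- NULL
  for (th in c(1.3, 1.5, 1.8, 2.2)) {
    deg <- call_degs(sim$contrast, mk_symbols(400), threshold = th)
    if (!is.null(prev_up)) {
      expect_true(all(deg$up %in% prev_up))
      expect_true(all(deg$down %in% prev_down))
    }
    prev_up <- deg$up; prev_down <- deg$down
  }
})

test_that("contrast ingestion handles precomputed fc, log2 and bad rows", {
  df <- data.frame(feature_id = c("p1", "p2"), symbol = c("A", "B"),
                   signed_fc = c(2, -1.5))
  ct <- as_contrast(df, "d1")
  expect_equal(ct$rows$signed_fc, c(2, -1.5))
  expect_error(as_contrast(data.frame(feature_id = "p", symbol = "A",
                                      signed_fc = 0.5), "d"),
               "magnitude")
  log2df <- data.frame(feature_id = c("p1", "p2"), symbol = c("A", "B"),
                       treat_mean = c(3, 1), control_mean = c(2, 2))
  ct2 <- as_contrast(log2df, "d2", log2_input = TRUE)
  expect_equal(ct2$rows$signed_fc, c(2, -2))
  expect_warning(
    ct3 <- as_contrast(data.frame(feature_id = c("p1", "p2"),
                                  symbol = c("A", ""),
                                  treat_mean = c(3, 3),
                                  control_mean = c(2, 2)), "d3"),
    "dropped")
  expect_identical(ct3$n_dropped, 1L)

  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast(ct, path)
  back <- read_contrast(path, dataset_id = "d1")
  expect_equal(back$rows$signed_fc, ct$rows$signed_fc)
})
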