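# Shared fixture builders. All fixtures are constructed in code; contrasts
# get stable housekeeping rows by default so QC passes unless a test says
# otherwise.

# contrast from named fold changes (names = symbols)
mk_contrast <- function(fc, id = "test", species = "agnostic",
                        housekeeping = TRUE, hk_fc = c(1.076, -1.015,
                                                       1.013, 1.009)) {
  sym <- names(fc)
  if (housekeeping) {
    extra <- setdiff(HOUSEKEEPING_GENES, sym)
    fc <- c(fc, stats::setNames(hk_fc[seq_along(extra)], extra))
    sym <- names(fc)
  }
  control <- rep(100, length(sym))
  treat <- ifelse(fc >= 0, control * fc, control / abs(fc))
  with_qc(as_contrast(data.frame(feature_id = paste0(sym, "_p1"),
                                 symbol = sym, treat_mean = treat,
                                 control_mean = control,
                                 stringsAsFactors = FALSE),
                      dataset_id = id, species = species))
}

# plain catalog of n unannotated symbols
mk_symbols <- function(n, prefix = "G") sprintf("%s%04d", prefix, seq_len(n))

# brute-force two-sided Fisher p for a 2x2 via hypergeometric enumeration:
# sum of P(X = x) over all x whose pmf is <= the observed pmf
oracle_fisher2sided <- function(k, K, n, N) {
  x <- max(0L, n - (N - K)):min(K, n)
  pmf <- stats::dhyper(x, K, N - K, n)
  obs <- stats::dhyper(k, K, N - K, n)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# brute-force two-sample KS D by sweeping every pooled point
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# independent truth-table oracle for the ROS four-group rule ("any" mode)
oracle_ros_group <- function(ko_type, direction) {
  prom <- any(ko_type == "NOX2" & direction == "down") ||
    any(ko_type == "Nrf2" & direction == "up")
  supp <- any(ko_type == "NOX2" & direction == "up") ||
    any(ko_type == "Nrf2" & direction == "down")
  if (prom && supp) "uncertain"
  else if (prom) "promoted"
  else if (supp) "suppressed"
  else "independent"
}
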