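# Differential-expression calling from signed fold changes.
#
# A contrast is one treatment-vs-control comparison, held as per-feature
# linear-scale group means plus a signed fold change with magnitude >= 1:
# treat/control when treatment is the higher group, -(control/treat)
# otherwise, so -1.151 means a 1.151-fold decrease. Genes moving at least
# 1.5-fold in either direction are called up/down-regulated; dataset quality
# is gated on four housekeeping genes (CHMP2A, PSMB4, ACTB, GAPDH) staying
# below the same 1.5-fold bound.

#' Signed fold change between two positive expression values
#'
#' Returns `treat/control` when `treat >= control`, else
#' `-(control/treat)`; magnitude is always >= 1 and the sign encodes
#' direction (negative = decrease under treatment). Inputs are linear-scale
#' group means. Vectorized.
#'
#' @param treat_mean,control_mean positive numeric vectors.
#' @return numeric vector of signed fold changes.
#' @export
#' @examples
#' signed_fold_change(3, 2)   # +1.5
#' signed_fold_change(2, 3)   # -1.5
signed_fold_change <- function(treat_mean, control_mean) {
  if (any(!is.finite(treat_mean)) || any(!is.finite(control_mean)) ||
      any(treat_mean <= 0) || any(control_mean <= 0)) {
    stop("expression means must be positive and finite", call. = FALSE)
  }
  ifelse(treat_mean >= control_mean,
         treat_mean / control_mean,
         -control_mean / treat_mean)
}

new_contrast <- function(dataset_id, species, rows, qc = NULL,
                         ambiguous = character(0), n_dropped = 0L) {
  structure(list(dataset_id = dataset_id, species = species, rows = rows,
                 qc = qc, ambiguous = ambiguous, n_dropped = n_dropped),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat("<contrast> ", x$dataset_id, " (", x$species, "): ",
      nrow(x$rows), " genes", sep = "")
  if (length(x$ambiguous)) cat(";", length(x$ambiguous), "ambiguous")
  if (!is.null(x$qc)) cat("; QC", if (x$qc$pass) "pass" else "FAIL")
  cat("\n")
  invisible(x)
}

#' Build a contrast from a per-feature table
#'
#' @param df data.frame with columns `feature_id`, `symbol` and either
#'   `treat_mean`+`control_mean` or a precomputed `signed_fc`.
#' @param dataset_id identifier for the comparison (e.g. a GEO accession).
#' @param species species tag.
#' @param log2_input if `TRUE`, `treat_mean`/`control_mean` are log2 values
#'   and are exponentiated before ratioing.
#' @param collapse collapse probe-level rows to gene level (see
#'   [collapse_probes()]); default `TRUE`.
#' @return a `contrast` object with gene-level rows
#'   (`feature_id`, `symbol`, `treat_mean`, `control_mean`, `signed_fc`).
#' @export
as_contrast <- function(df, dataset_id, species = "agnostic",
                        log2_input = FALSE, collapse = TRUE) {
  species <- match.arg(species, SPECIES_TAGS)
  need <- c("feature_id", "symbol")
  if (!all(need %in% names(df))) {
    stop("contrast table needs columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(df$symbol) & trimws(df$symbol) != ""
  n_dropped <- sum(!keep)
  if (n_dropped) {
    warning(n_dropped, " row(s) without a gene symbol dropped",
            call. = FALSE)
  }
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable rows in contrast table", call. = FALSE)
  df$symbol <- canonicalize_symbol(df$symbol, species)
  if (all(c("treat_mean", "control_mean") %in% names(df))) {
    if (log2_input) {
      df$treat_mean <- 2^df$treat_mean
      df$control_mean <- 2^df$control_mean
    }
    df$signed_fc <- signed_fold_change(df$treat_mean, df$control_mean)
  } else if ("signed_fc" %in% names(df)) {
    if (any(abs(df$signed_fc) < 1)) {
      stop("precomputed signed_fc must have magnitude >= 1", call. = FALSE)
    }
    # reconstruct nominal means so the container invariant holds
    df$control_mean <- rep(1, nrow(df))
    df$treat_mean <- ifelse(df$signed_fc >= 0, df$signed_fc,
                            -1 / df$signed_fc)
  } else {
    stop("need treat_mean+control_mean or signed_fc columns", call. = FALSE)
  }
  cols <- c("feature_id", "symbol", "treat_mean", "control_mean", "signed_fc")
  df <- df[, cols]
  ambiguous <- character(0)
  if (collapse) {
    coll <- collapse_probes(df)
    df <- coll$rows
    ambiguous <- coll$ambiguous
  }
  rownames(df) <- NULL
  new_contrast(dataset_id, species, df, ambiguous = ambiguous,
               n_dropped = n_dropped)
}

#' Read a contrast TSV
#'
#' Columns `feature_id`, `symbol`, `treat_mean`, `control_mean` (or
#' `signed_fc` directly). See [as_contrast()] for options.
#'
#' @inheritParams as_contrast
#' @param path path to the tab-separated file.
#' @return a `contrast`.
#' @export
read_contrast <- function(path, dataset_id = basename(path),
                          species = "agnostic", log2_input = FALSE,
                          collapse = TRUE) {
  as_contrast(read_tsv_strict(path), dataset_id = dataset_id,
              species = species, log2_input = log2_input,
              collapse = collapse)
}

#' Write a gene-level contrast to TSV
#' @param contrast a `contrast`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "contrast"))
  write_tsv_plain(contrast$rows, path)
}

#' Collapse probe-level rows to gene level
#'
#' One record per symbol, keeping the probe with the largest absolute signed
#' fold change. If two probes tie in magnitude with opposite signs the gene's
#' direction is undecidable and it is reported as ambiguous (and removed from
#' the collapsed rows).
#'
#' @param rows data.frame with columns `feature_id`, `symbol`, `treat_mean`,
#'   `control_mean`, `signed_fc`.
#' @return list with `rows` (gene-level data.frame) and `ambiguous`
#'   (character vector of undecidable symbols).
#' @export
collapse_probes <- function(rows) {
  stopifnot(all(c("symbol", "signed_fc") %in% names(rows)))
  ord <- order(rows$symbol, -abs(rows$signed_fc), rows$signed_fc)
  rows <- rows[ord, , drop = FALSE]
  first <- !duplicated(rows$symbol)
  best <- rows[first, , drop = FALSE]
  # a gene is ambiguous when its max |fc| is attained with both signs
  key_pos <- paste0(rows$symbol, "@", abs(rows$signed_fc))
  has_pos <- unique(key_pos[rows$signed_fc > 0])
  has_neg <- unique(key_pos[rows$signed_fc < 0])
  best_key <- paste0(best$symbol, "@", abs(best$signed_fc))
  ambiguous <- best$symbol[best_key %in% has_pos & best_key %in% has_neg]
  rows_out <- best[!best$symbol %in% ambiguous, , drop = FALSE]
  rows_out <- rows_out[order(rows_out$symbol), , drop = FALSE]
  rownames(rows_out) <- NULL
  list(rows = rows_out, ambiguous = sort(ambiguous))
}

#' Housekeeping-gene quality control
#'
#' A contrast passes QC when all housekeeping genes are present and each has
#' `|signed_fc| < qc_threshold`. In the source datasets these four genes
#' varied only between -1.27 and 1.28. A missing housekeeping gene fails QC
#' (reason "absent") rather than raising an error.
#'
#' @param contrast a `contrast` with gene-level rows.
#' @param housekeeping a `gene_catalog` or character vector of symbols;
#'   default the canonical four ([HOUSEKEEPING_GENES]).
#' @param qc_threshold fold-change bound (default 1.5, the DEG threshold).
#' @return a `qc_report` list: `values` (named signed fc, `NA` if absent),
#'   `max_abs_fc`, `missing`, `pass`, `qc_threshold`.
#' @export
housekeeping_qc <- function(contrast, housekeeping = HOUSEKEEPING_GENES,
                            qc_threshold = 1.5) {
  stopifnot(inherits(contrast, "contrast"), qc_threshold > 1)
  hk <- if (inherits(housekeeping, "gene_catalog")) housekeeping$genes
        else canonicalize_symbol(housekeeping)
  idx <- match(hk, contrast$rows$symbol)
  values <- stats::setNames(contrast$rows$signed_fc[idx], hk)
  missing <- hk[is.na(idx)]
  max_abs <- if (all(is.na(values))) NA_real_ else max(abs(values), na.rm = TRUE)
  pass <- length(missing) == 0L && all(abs(values) < qc_threshold)
  structure(list(values = values, max_abs_fc = max_abs, missing = missing,
                 pass = pass, qc_threshold = qc_threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", if (x$pass) "PASS" else "FAIL",
      "(threshold", paste0(x$qc_threshold, ")"), "\n")
  for (g in names(x$values)) {
    cat("  ", g, ": ",
        if (is.na(x$values[[g]])) "absent" else
          format(x$values[[g]], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Attach a QC report to a contrast
#' @inheritParams housekeeping_qc
#' @return the `contrast` with its `qc` field set.
#' @export
with_qc <- function(contrast, housekeeping = HOUSEKEEPING_GENES,
                    qc_threshold = 1.5) {
  contrast$qc <- housekeeping_qc(contrast, housekeeping, qc_threshold)
  contrast
}

#' Call differentially expressed genes against a catalog
#'
#' Members of `catalog` with `signed_fc >= threshold` are called up, those
#' with `signed_fc <= -threshold` down; the boundary is included (a gene at
#' exactly 1.5-fold is called). Requires a passing housekeeping QC (run
#' automatically when absent) unless `override_qc = TRUE`.
#'
#' @param contrast a `contrast`.
#' @param catalog a `gene_catalog` delimiting the gene universe, or a
#'   character vector of symbols.
#' @param threshold fold-change cutoff (default 1.5).
#' @param override_qc proceed despite QC failure (logged with a warning).
#' @return a `deg_result` list: `up`, `down` (sorted symbol vectors),
#'   `threshold`, `ambiguous` (catalog genes excluded by the probe-collapse
#'   tie rule), `dataset_id`, `catalog_total`.
#' @export
call_degs <- function(contrast, catalog, threshold = 1.5,
                      override_qc = FALSE) {
  stopifnot(inherits(contrast, "contrast"), threshold > 1)
  genes <- if (inherits(catalog, "gene_catalog")) catalog$genes
           else canonicalize_symbol(catalog)
  if (is.null(contrast$qc)) contrast <- with_qc(contrast)
  if (!contrast$qc$pass) {
    if (!override_qc) {
      cond <- structure(
        class = c("qc_failure", "error", "condition"),
        list(message = paste0("housekeeping QC failed for ",
                              contrast$dataset_id,
                              " (use override_qc = TRUE to force)"),
             call = sys.call(-1), qc = contrast$qc))
      stop(cond)
    }
    warning("QC failure overridden for ", contrast$dataset_id,
            call. = FALSE)
  }
  rows <- contrast$rows[contrast$rows$symbol %in% genes, , drop = FALSE]
  structure(list(
    up = sort(rows$symbol[rows$signed_fc >= threshold]),
    down = sort(rows$symbol[rows$signed_fc <= -threshold]),
    threshold = threshold,
    ambiguous = sort(intersect(contrast$ambiguous, genes)),
    dataset_id = contrast$dataset_id,
    catalog_total = length(genes)), class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("<deg_result> ", x$dataset_id, ": ", length(x$up), " up / ",
      length(x$down), " down of ", x$catalog_total,
      " catalog genes at |fc| >= ", x$threshold, "\n", sep = "")
  invisible(x)
}
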