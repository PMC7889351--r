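# Profiling DEG calls against catalogs: headline fractions, composition
# comparisons, Venn partitions and targeted gene-panel scans.

#' Percentage of a catalog, rendered
#'
#' `100 * count / total` rounded half-up at `decimals` places: the rendering
#' used for headline fractions like 77/1376 -> 5.6\% (1 decimal) and
#' composition tables like 481/1376 -> 34.96\% (2 decimals).
#'
#' @param count non-negative integer(s), at most `total`.
#' @param total positive integer.
#' @param decimals decimal places (default 1).
#' @return percentage(s) on the 0-100 scale.
#' @export
percent_of_catalog <- function(count, total, decimals = 1) {
  stopifnot(length(total) == 1L, total > 0, all(count >= 0))
  if (any(count > total)) stop("count exceeds total", call. = FALSE)
  pct_render(count, total, decimals)
}

#' Package one direction of a DEG call as a reference set
#'
#' A modulated set is the reference object used in concordance analysis: the
#' genes one dataset moved in one direction, with the catalog denominator.
#'
#' @param deg a `deg_result` from [call_degs()].
#' @param direction `"up"` or `"down"`.
#' @return a `modulated_set` list: `dataset_id`, `direction`, `genes`,
#'   `catalog_total`, `percent` (1-decimal).
#' @export
modulated_set <- function(deg, direction = c("up", "down")) {
  stopifnot(inherits(deg, "deg_result"))
  direction <- match.arg(direction)
  genes <- deg[[direction]]
  structure(list(dataset_id = deg$dataset_id, direction = direction,
                 genes = genes, catalog_total = deg$catalog_total,
                 percent = percent_of_catalog(length(genes),
                                              deg$catalog_total, 1)),
            class = "modulated_set")
}

#' @export
print.modulated_set <- function(x, ...) {
  cat("<modulated_set> ", x$dataset_id, " ", x$direction, ": ",
      length(x$genes), "/", x$catalog_total, " (", x$percent, "%)\n",
      sep = "")
  invisible(x)
}

#' Compare category composition of a subset against its catalog
#'
#' Per category, a two-sided Fisher exact test on the 2x2 table
#' (in-category vs not) x (in-subset vs rest-of-catalog), flagged at `alpha`.
#' The background is the whole catalog (subset included), matching how the
#' source composition tables juxtapose whole-catalog columns against DEG
#' subsets. No multiple-testing correction by default (per-category alpha
#' asterisks); `adjust = "BH"` applies Benjamini-Hochberg before flagging.
#'
#' @param subset character vector of catalog symbols (non-empty).
#' @param catalog annotated `gene_catalog`.
#' @param scheme `"location"` or `"function"`.
#' @param alpha flagging level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per category: `category`, `subset_count`,
#'   `subset_pct`, `background_count`, `background_pct`, `p_value`, `flagged`.
#' @export
compare_composition <- function(subset, catalog,
                                scheme = c("location", "function"),
                                alpha = 0.05, adjust = c("none", "BH")) {
  scheme <- match.arg(scheme)
  adjust <- match.arg(adjust)
  if (length(subset) == 0L) stop("subset is empty", call. = FALSE)
  sub_comp <- category_composition(catalog, subset, scheme)
  bg_comp <- category_composition(catalog, NULL, scheme)
  n_sub <- attr(sub_comp, "total")
  n_bg <- attr(bg_comp, "total")
  n_rest <- n_bg - n_sub
  p <- mapply(function(k_sub, k_bg) {
    # 2x2: rows = in-category / not, cols = subset / rest-of-catalog
    m <- matrix(c(k_sub, n_sub - k_sub,
                  k_bg - k_sub, n_rest - (k_bg - k_sub)), nrow = 2L)
    if (n_rest == 0L) return(1)  # subset == catalog: nothing to compare
    stats::fisher.test(m)$p.value
  }, sub_comp$count, bg_comp$count)
  p_flag <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.frame(category = sub_comp$category,
             subset_count = sub_comp$count,
             subset_pct = sub_comp$percent,
             background_count = bg_comp$count,
             background_pct = bg_comp$percent,
             p_value = p,
             flagged = p_flag < alpha,
             stringsAsFactors = FALSE)
}

#' Exclusive Venn partition of 2 to 5 sets
#'
#' Counts every exclusive region of the Venn diagram; region names join the
#' member set names with `"&"` (a region counts elements in exactly those
#' sets and no others). Region counts sum to the size of the union.
#'
#' @param sets named list of 2-5 character vectors.
#' @return named integer vector over all `2^k - 1` regions.
#' @export
#' @examples
#' venn_partition(list(L = c("A", "B", "C"), B = c("B", "C", "D")))
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 5L) stop("need between 2 and 5 sets", call. = FALSE)
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  masks <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  region_names <- apply(masks, 1L, function(m) paste(nms[unlist(m)],
                                                     collapse = "&"))
  counts <- apply(masks, 1L, function(m) {
    sum(apply(member, 1L, function(row) all(row == unlist(m))))
  })
  if (length(universe) == 0L) counts <- rep(0L, nrow(masks))
  stats::setNames(as.integer(counts), region_names)
}

#' Scan a gene panel across contrasts
#'
#' Counts panel genes moving up/down (at `threshold`) in each contrast and
#' pooled across contrasts (unique genes, since the same panel gene may
#' respond in several cell types). Reports both direction ratios; a ratio is
#' `NA` when its denominator is zero.
#'
#' @param contrasts a `contrast` or list of `contrast` objects.
#' @param panel `gene_catalog` or character vector (non-empty).
#' @param threshold fold-change cutoff (default 1.5).
#' @return a `panel_scan` list: `panel`, `panel_size`, `per_contrast`
#'   (data.frame `dataset_id`, `n_up`, `n_down`), `pooled_up`, `pooled_down`
#'   (unique symbols), `ratio_down_over_up`, `ratio_up_over_down`.
#' @export
panel_scan <- function(contrasts, panel, threshold = 1.5) {
  if (inherits(contrasts, "contrast")) contrasts <- list(contrasts)
  stopifnot(length(contrasts) >= 1L,
            all(vapply(contrasts, inherits, TRUE, "contrast")))
  genes <- if (inherits(panel, "gene_catalog")) panel$genes
           else canonicalize_symbol(panel)
  if (length(genes) == 0L) stop("panel is empty", call. = FALSE)
  per <- lapply(contrasts, function(ct) {
    rows <- ct$rows[ct$rows$symbol %in% genes, , drop = FALSE]
    list(dataset_id = ct$dataset_id,
         up = sort(rows$symbol[rows$signed_fc >= threshold]),
         down = sort(rows$symbol[rows$signed_fc <= -threshold]))
  })
  pooled_up <- sort(unique(unlist(lapply(per, `[[`, "up"))))
  pooled_down <- sort(unique(unlist(lapply(per, `[[`, "down"))))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    panel = if (inherits(panel, "gene_catalog")) panel$name else "panel",
    panel_size = length(genes),
    per_contrast = data.frame(
      dataset_id = vapply(per, `[[`, "", "dataset_id"),
      n_up = vapply(per, function(x) length(x$up), 0L),
      n_down = vapply(per, function(x) length(x$down), 0L),
      stringsAsFactors = FALSE),
    pooled_up = pooled_up,
    pooled_down = pooled_down,
    ratio_down_over_up = ratio(length(pooled_down), length(pooled_up)),
    ratio_up_over_down = ratio(length(pooled_up), length(pooled_down))),
    class = "panel_scan")
}

#' @export
print.panel_scan <- function(x, ...) {
  cat("<panel_scan> ", x$panel, " (", x$panel_size, " genes): pooled ",
      length(x$pooled_up), " up / ", length(x$pooled_down), " down\n",
      sep = "")
  print(x$per_contrast)
  invisible(x)
}
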