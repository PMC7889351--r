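# Cross-dataset directional concordance and mechanism ranking.
#
# A reference set (genes one treatment moved in one direction) is followed
# into perturbation contrasts -- shear stress / hyperthermia, cytokine
# knockouts, immune-checkpoint-receptor overexpression, ROS-pathway
# knockouts -- and each reference gene is binned by the perturbation's signed
# fold change. Mechanisms are ranked by the fraction of reference genes
# responsive in at least one of the mechanism's datasets.

#' Directional concordance of a reference set in a perturbation contrast
#'
#' Each reference gene is binned by the perturbation's signed fold change at
#' `threshold`: up, down, unchanged, or unmeasured (absent from the
#' perturbation platform). Percentages use the full reference size as
#' denominator by default (matching headline figures like "10.4% of 77");
#' `measured_denominator = TRUE` restricts to measured genes.
#'
#' @param reference a `modulated_set` (see [modulated_set()]) or a list with
#'   at least `genes` and `dataset_id`.
#' @param perturbation a `contrast`.
#' @param threshold fold-change cutoff (default 1.5).
#' @param measured_denominator exclude unmeasured genes from the percentage
#'   denominator (default `FALSE`).
#' @return a `concordance_cell` list: ids, `size`, `n_up`, `n_down`,
#'   `n_unchanged`, `n_unmeasured`, `pct_up`, `pct_down` (1-decimal), and the
#'   binned symbols `genes_up`, `genes_down`.
#' @export
concordance <- function(reference, perturbation, threshold = 1.5,
                        measured_denominator = FALSE) {
  stopifnot(inherits(perturbation, "contrast"), threshold > 1)
  genes <- unique(reference$genes)
  if (length(genes) == 0L) stop("reference set is empty", call. = FALSE)
  fc <- perturbation$rows$signed_fc[match(genes, perturbation$rows$symbol)]
  up <- !is.na(fc) & fc >= threshold
  down <- !is.na(fc) & fc <= -threshold
  unmeasured <- is.na(fc)
  unchanged <- !up & !down & !unmeasured
  denom <- if (measured_denominator) sum(!unmeasured) else length(genes)
  structure(list(
    reference_id = reference$dataset_id %||% "reference",
    direction = reference$direction %||% NA_character_,
    perturbation_id = perturbation$dataset_id,
    size = length(genes),
    n_up = sum(up), n_down = sum(down),
    n_unchanged = sum(unchanged), n_unmeasured = sum(unmeasured),
    pct_up = if (denom > 0) pct_render(sum(up), denom, 1) else NA_real_,
    pct_down = if (denom > 0) pct_render(sum(down), denom, 1) else NA_real_,
    genes_up = sort(genes[up]), genes_down = sort(genes[down])),
    class = "concordance_cell")
}

#' @export
print.concordance_cell <- function(x, ...) {
  cat("<concordance_cell> ", x$reference_id,
      if (!is.na(x$direction)) paste0("/", x$direction), " in ",
      x$perturbation_id, ": ", x$n_up, " up (", x$pct_up, "%), ",
      x$n_down, " down (", x$pct_down, "%) of ", x$size, "\n", sep = "")
  invisible(x)
}

#' Concordance of every reference in every perturbation
#'
#' @param references list of `modulated_set` objects.
#' @param perturbations list of `contrast` objects.
#' @inheritParams concordance
#' @return a `concordance_matrix`: list of `concordance_cell`, row-major
#'   (references outer, perturbations inner), with a `summary` data.frame
#'   attribute-free accessor via [as.data.frame()].
#' @export
concordance_matrix <- function(references, perturbations, threshold = 1.5,
                               measured_denominator = FALSE) {
  if (inherits(references, "modulated_set")) references <- list(references)
  if (inherits(perturbations, "contrast")) perturbations <- list(perturbations)
  stopifnot(length(references) >= 1L, length(perturbations) >= 1L)
  cells <- list()
  for (ref in references) {
    for (pert in perturbations) {
      cells[[length(cells) + 1L]] <-
        concordance(ref, pert, threshold, measured_denominator)
    }
  }
  structure(cells, class = "concordance_matrix")
}

#' @export
as.data.frame.concordance_matrix <- function(x, ...) {
  do.call(rbind, lapply(x, function(cell) {
    data.frame(reference_id = cell$reference_id,
               direction = cell$direction,
               perturbation_id = cell$perturbation_id,
               size = cell$size, n_up = cell$n_up, n_down = cell$n_down,
               n_unchanged = cell$n_unchanged,
               n_unmeasured = cell$n_unmeasured,
               pct_up = cell$pct_up, pct_down = cell$pct_down,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.concordance_matrix <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Rank candidate mechanisms by related fraction
#'
#' For each mechanism, the related fraction is 100 times the number of
#' (reference, gene) pairs responsive (up or down at threshold) in at least
#' one of the mechanism's datasets, divided by the total number of
#' (reference, gene) pairs, pooled over references. Duplicating a
#' mechanism's dataset cannot change its fraction (union semantics). Output
#' is sorted descending with alphabetical tie-break.
#'
#' @param cells a `concordance_matrix`.
#' @param grouping named character vector mapping every perturbation
#'   `dataset_id` to a mechanism label (e.g. `"ros"`, `"checkpoint"`,
#'   `"cytokine"`, `"shear_heat"`).
#' @return a `mechanism_ranking` data.frame: `mechanism`, `n_responsive`,
#'   `n_total`, `related_fraction` (1-decimal, 0-100), ordered by rank.
#' @export
rank_mechanisms <- function(cells, grouping) {
  stopifnot(inherits(cells, "concordance_matrix"))
  pert_ids <- unique(vapply(cells, `[[`, "", "perturbation_id"))
  unassigned <- setdiff(pert_ids, names(grouping))
  if (length(unassigned)) {
    stop("perturbation dataset(s) without a mechanism: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  ref_key <- function(cell) paste0(cell$reference_id, "/", cell$direction)
  # pooled denominator: every (reference, gene) pair, counted once
  refs <- unique(vapply(cells, ref_key, ""))
  ref_sizes <- vapply(refs, function(r) {
    cells[[which(vapply(cells, ref_key, "") == r)[1L]]]$size
  }, 0L)
  n_total <- sum(ref_sizes)
  mechs <- sort(unique(unname(grouping[pert_ids])))
  rows <- lapply(mechs, function(m) {
    in_mech <- vapply(cells, function(cell) {
      grouping[[cell$perturbation_id]] == m
    }, TRUE)
    responsive <- 0L
    for (r in refs) {
      sel <- in_mech & vapply(cells, ref_key, "") == r
      hit <- unique(unlist(lapply(cells[sel],
                                  function(cell) c(cell$genes_up,
                                                   cell$genes_down))))
      responsive <- responsive + length(hit)
    }
    data.frame(mechanism = m, n_responsive = responsive, n_total = n_total,
               related_fraction = pct_render(responsive, n_total, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # descending fraction; stable alphabetical order on ties (mechs is sorted)
  out <- out[order(-out$related_fraction, out$mechanism), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mechanism_ranking", "data.frame")
  out
}
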