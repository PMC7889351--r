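# Rule-based four-group ROS-dependency classification.
#
# Evidence comes from perturbation contrasts in which the ROS-generating
# oxidase NOX2 or the antioxidant transcription factor Nrf2 has been knocked
# out. A gene whose expression drops when NOX2 is lost, or rises when Nrf2
# (which restrains ROS) is lost, behaves as ROS-promoted; the mirror pattern
# is ROS-suppressed; conflicting evidence is uncertain; no response in any
# KO dataset is ROS-independent.

ROS_GROUPS <- c("promoted", "suppressed", "uncertain", "independent")
KO_TYPES <- c("NOX2", "Nrf2")

#' Classify one gene's ROS dependency from KO evidence
#'
#' Evidence is a table of per-dataset response directions. Promoted-evidence
#' is (down in a NOX2-KO dataset) or (up in an Nrf2-KO dataset);
#' suppressed-evidence is the mirror image. Default mode `"any"` assigns
#' promoted/suppressed on evidence of only one kind, uncertain when both
#' kinds are present, independent when neither. Mode `"strict"` additionally
#' requires concordant evidence from *both* KO types for a
#' promoted/suppressed call (single-sided evidence falls back to uncertain).
#'
#' @param evidence data.frame with columns `dataset_id`, `ko_type`
#'   (`"NOX2"` or `"Nrf2"`), `direction` (`"up"`, `"down"`, `"unchanged"`).
#' @param mode `"any"` (default) or `"strict"`.
#' @return one of `"promoted"`, `"suppressed"`, `"uncertain"`,
#'   `"independent"`.
#' @export
#' @examples
#' classify_gene(data.frame(dataset_id = c("n1", "f1"),
#'                          ko_type = c("NOX2", "Nrf2"),
#'                          direction = c("down", "up")))   # "promoted"
classify_gene <- function(evidence, mode = c("any", "strict")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(evidence), nrow(evidence) >= 1L,
            all(c("ko_type", "direction") %in% names(evidence)))
  if (!all(evidence$ko_type %in% KO_TYPES)) {
    stop("unknown ko_type: ",
         paste(setdiff(evidence$ko_type, KO_TYPES), collapse = ", "),
         call. = FALSE)
  }
  if (!all(evidence$direction %in% c("up", "down", "unchanged"))) {
    stop("direction must be up/down/unchanged", call. = FALSE)
  }
  nox_up <- any(evidence$ko_type == "NOX2" & evidence$direction == "up")
  nox_dn <- any(evidence$ko_type == "NOX2" & evidence$direction == "down")
  nrf_up <- any(evidence$ko_type == "Nrf2" & evidence$direction == "up")
  nrf_dn <- any(evidence$ko_type == "Nrf2" & evidence$direction == "down")
  promoted <- nox_dn || nrf_up
  suppressed <- nox_up || nrf_dn
  if (promoted && suppressed) return("uncertain")
  if (!promoted && !suppressed) return("independent")
  if (mode == "strict") {
    ok <- if (promoted) nox_dn && nrf_up else nox_up && nrf_dn
    if (!ok) return("uncertain")
  }
  if (promoted) "promoted" else "suppressed"
}

#' Classify a gene set from NOX2-KO and Nrf2-KO contrasts
#'
#' Builds per-gene evidence by thresholding each KO contrast's signed fold
#' change at `threshold` (genes absent from a contrast count as unchanged
#' there), applies [classify_gene()], and summarizes the four-group
#' partition. The "ROS-related" fraction is 100 minus the independent
#' percentage.
#'
#' @param genes character vector of symbols (non-empty).
#' @param nox2 a `contrast` or list of contrasts from NOX2-deficient cells.
#' @param nrf2 a `contrast` or list of contrasts from Nrf2-deficient cells.
#' @param threshold fold-change cutoff (default 1.5).
#' @param mode passed to [classify_gene()].
#' @return a `ros_classification` list: `assignments` (data.frame `gene`,
#'   `group`), `counts`, `percent` (named, 1-decimal), `ros_related`
#'   (0-100), `n`, `mode`.
#' @export
classify_set <- function(genes, nox2 = list(), nrf2 = list(),
                         threshold = 1.5, mode = c("any", "strict")) {
  mode <- match.arg(mode)
  genes <- unique(canonicalize_symbol(genes))
  if (length(genes) == 0L) stop("gene set is empty", call. = FALSE)
  if (inherits(nox2, "contrast")) nox2 <- list(nox2)
  if (inherits(nrf2, "contrast")) nrf2 <- list(nrf2)
  if (length(nox2) + length(nrf2) == 0L) {
    stop("need at least one NOX2-KO or Nrf2-KO contrast", call. = FALSE)
  }
  direction_in <- function(ct, g) {
    fc <- ct$rows$signed_fc[match(g, ct$rows$symbol)]
    ifelse(is.na(fc), "unchanged",
           ifelse(fc >= threshold, "up",
                  ifelse(fc <= -threshold, "down", "unchanged")))
  }
  ev_list <- c(
    lapply(nox2, function(ct) {
      data.frame(dataset_id = ct$dataset_id, ko_type = "NOX2",
                 gene = genes, direction = direction_in(ct, genes),
                 stringsAsFactors = FALSE)
    }),
    lapply(nrf2, function(ct) {
      data.frame(dataset_id = ct$dataset_id, ko_type = "Nrf2",
                 gene = genes, direction = direction_in(ct, genes),
                 stringsAsFactors = FALSE)
    }))
  ev <- do.call(rbind, ev_list)
  group <- vapply(genes, function(g) {
    classify_gene(ev[ev$gene == g, , drop = FALSE], mode = mode)
  }, "")
  counts <- vapply(ROS_GROUPS, function(gr) sum(group == gr), 0L)
  percent <- pct_render(counts, length(genes), 1)
  names(percent) <- ROS_GROUPS
  structure(list(
    assignments = data.frame(gene = genes, group = unname(group),
                             stringsAsFactors = FALSE),
    counts = counts, percent = percent,
    ros_related = round_half_up(100 - percent[["independent"]], 1),
    n = length(genes), mode = mode), class = "ros_classification")
}

#' @export
print.ros_classification <- function(x, ...) {
  cat("<ros_classification> n =", x$n, "(mode", paste0(x$mode, ")\n"))
  for (g in ROS_GROUPS) {
    cat(sprintf("  %-12s %4d  (%.1f%%)\n", g, x$counts[[g]], x$percent[[g]]))
  }
  cat(sprintf("  ROS-related: %.1f%%\n", x$ros_related))
  invisible(x)
}
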