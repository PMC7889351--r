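# Hypergeometric over-representation against a GMT collection.
#
# Generic stand-in for commercial pathway tools: given a query gene set and a
# universe (by default the innatome catalog), each pathway is tested for
# over-representation with the upper-tail hypergeometric distribution, and
# p-values are adjusted across tested pathways with Benjamini-Hochberg.

#' Hypergeometric gene-set enrichment
#'
#' Pathways are intersected with the universe before testing; pathways with
#' fewer than `min_size` genes after intersection are skipped (recorded in
#' attribute `"skipped"`). The p-value is `P(overlap >= observed)` drawing
#' `|query|` genes from the universe without replacement.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param collection named list of pathway gene vectors (see [read_gmt()]).
#' @param universe character vector of background genes, or a `gene_catalog`.
#' @param min_size minimum post-intersection pathway size (default 3).
#' @return data.frame sorted by ascending p-value with columns `pathway`,
#'   `overlap_count`, `pathway_size`, `universe_size`, `query_size`,
#'   `p_value`, `bh_fdr`.
#' @export
hypergeom_enrich <- function(query, collection, universe, min_size = 3L) {
  if (inherits(universe, "gene_catalog")) universe <- universe$genes
  universe <- unique(canonicalize_symbol(universe))
  query <- unique(canonicalize_symbol(query))
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  if (length(query) == 0L) stop("query is empty", call. = FALSE)
  stray <- setdiff(query, universe)
  if (length(stray)) {
    stop("query genes outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(collection) == 0L || is.null(names(collection))) {
    stop("collection must be a non-empty named list", call. = FALSE)
  }
  sets <- lapply(collection, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  skipped <- names(sets)[sizes < min_size]
  sets <- sets[sizes >= min_size]
  if (length(skipped)) {
    message(length(skipped), " pathway(s) smaller than ", min_size,
            " after universe intersection skipped")
  }
  if (length(sets) == 0L) {
    out <- data.frame(pathway = character(0), overlap_count = integer(0),
                      pathway_size = integer(0), universe_size = integer(0),
                      query_size = integer(0), p_value = numeric(0),
                      bh_fdr = numeric(0), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  # upper tail including the observed overlap
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway = names(sets), overlap_count = k,
                    pathway_size = K, universe_size = N, query_size = n,
                    p_value = p, bh_fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
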