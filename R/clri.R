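# Chromatin long-range interaction (CLRI) distance analysis.
#
# Interaction records (two genomic loci in contact, from 3C/4C/5C/Hi-C
# compilations such as 4DGenome) are anchored to gene transcription start
# sites; the partner locus is reduced to its midpoint and the signed
# distance measured in gene orientation: negative when the partner lies
# upstream of the promoter, positive downstream. Distance distributions of
# two gene sets are compared with the two-sample Kolmogorov-Smirnov test.
#
# Coordinates are 0-based half-open internally; interaction TSVs are read as
# 1-based inclusive (start shifted by -1), BED anchors are already 0-based.

#' Read a 4DGenome-style interaction table
#'
#' Required columns: `InteractorAChr`, `InteractorAStart`, `InteractorAEnd`,
#' `InteractorBChr`, `InteractorBStart`, `InteractorBEnd`, `Agg_Gene_A`,
#' `Agg_Gene_B`; optional `Detection_Method`, `Cell_Tissue`. Source
#' coordinates are 1-based inclusive and converted to 0-based half-open.
#' Malformed rows (non-numeric or empty intervals) are skipped and counted
#' in attribute `"n_skipped"`.
#'
#' @param path path to the tab-separated file.
#' @return data.frame of interaction records (attribute `n_skipped`).
#' @export
load_interactions <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("InteractorAChr", "InteractorAStart", "InteractorAEnd",
            "InteractorBChr", "InteractorBStart", "InteractorBEnd",
            "Agg_Gene_A", "Agg_Gene_B")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("interaction file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in grep("Start|End", need, value = TRUE)) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  # 1-based inclusive -> 0-based half-open: start-1, end unchanged
  for (col in c("InteractorAStart", "InteractorBStart")) {
    df[[col]] <- df[[col]] - 1
  }
  ok <- !is.na(df$InteractorAStart) & !is.na(df$InteractorAEnd) &
        !is.na(df$InteractorBStart) & !is.na(df$InteractorBEnd) &
        df$InteractorAStart < df$InteractorAEnd &
        df$InteractorBStart < df$InteractorBEnd
  n_skipped <- sum(!ok)
  if (n_skipped) {
    warning(n_skipped, " malformed interaction row(s) skipped",
            call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write interaction records back to 1-based inclusive TSV
#' @param records data.frame as returned by [load_interactions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(records, path) {
  df <- records
  for (col in c("InteractorAStart", "InteractorBStart")) {
    df[[col]] <- df[[col]] + 1
  }
  write_tsv_plain(df, path)
}

#' Read gene anchors from BED6
#'
#' BED is 0-based half-open; the TSS is `start` for `+`-strand genes and
#' `end - 1` for `-`-strand genes. The `name` field is the gene symbol.
#'
#' @param path path to a 6-column BED file (no header).
#' @param species species tag for symbol canonicalization.
#' @return data.frame `symbol`, `chrom`, `tss`, `strand`.
#' @export
read_anchors <- function(path, species = "agnostic") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("anchors must be BED6 (6 columns)", call. = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(df$strand %in% c("+", "-"))) {
    stop("BED strand must be '+' or '-'", call. = FALSE)
  }
  data.frame(symbol = canonicalize_symbol(df$name, species),
             chrom = df$chrom,
             tss = ifelse(df$strand == "+", df$start, df$end - 1),
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Write gene anchors as BED6
#'
#' Inverse of [read_anchors()]: each anchor becomes a 1-bp BED feature at
#' the TSS.
#'
#' @param anchors data.frame `symbol`, `chrom`, `tss`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  bed <- data.frame(chrom = anchors$chrom,
                    start = ifelse(anchors$strand == "+", anchors$tss,
                                   anchors$tss),
                    end = anchors$tss + 1,
                    name = anchors$symbol, score = 0,
                    strand = anchors$strand)
  # for "-" strand tss = end-1, so start = tss, end = tss+1 works for both
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# vectorized core: signed distance of partner [start, end) midpoints from a
# TSS, in gene orientation
signed_distance_core <- function(partner_start, partner_end, tss, strand,
                                 mode = c("midpoint", "nearest"),
                                 flip_sign = FALSE, strand_aware = TRUE) {
  mode <- match.arg(mode)
  point <- if (mode == "midpoint") {
    (partner_start + partner_end) / 2
  } else {
    # nearest edge of the partner interval to the TSS
    ifelse(tss < partner_start, partner_start,
           ifelse(tss >= partner_end, partner_end - 1, tss))
  }
  d <- point - tss
  if (strand_aware) d <- ifelse(strand == "-", -d, d)
  if (flip_sign) d <- -d
  d
}

#' Signed distance of an interaction partner from a gene TSS
#'
#' The partner interval is reduced to its midpoint (or nearest edge with
#' `mode = "nearest"`); the distance is measured from the anchor TSS and
#' oriented by strand, so a negative value means the partner lies upstream
#' of the promoter in gene orientation. `flip_sign` inverts the convention.
#'
#' @param record one row of an interaction table (see
#'   [load_interactions()]).
#' @param anchor one-row data.frame `symbol`, `chrom`, `tss`, `strand`.
#' @param partner_side `"A"` or `"B"`: which interactor is the partner.
#' @param mode `"midpoint"` (default) or `"nearest"`.
#' @param flip_sign invert the sign convention.
#' @param strand_aware orient by gene strand (default `TRUE`); `FALSE`
#'   reproduces a raw genomic-coordinate computation.
#' @return signed base-pair distance (numeric scalar).
#' @export
signed_distance <- function(record, anchor, partner_side = c("A", "B"),
                            mode = c("midpoint", "nearest"),
                            flip_sign = FALSE, strand_aware = TRUE) {
  partner_side <- match.arg(partner_side)
  chrom <- record[[paste0("Interactor", partner_side, "Chr")]]
  if (chrom != anchor$chrom) {
    stop("partner on ", chrom, " but anchor on ", anchor$chrom,
         " (trans interactions are excluded upstream)", call. = FALSE)
  }
  signed_distance_core(
    record[[paste0("Interactor", partner_side, "Start")]],
    record[[paste0("Interactor", partner_side, "End")]],
    anchor$tss, anchor$strand, mode = mode, flip_sign = flip_sign,
    strand_aware = strand_aware)
}

#' Signed CLRI distances for a gene set
#'
#' For every interaction record whose associated-gene field (`Agg_Gene_A` or
#' `Agg_Gene_B`) matches a requested gene, computes the signed distance from
#' that gene's TSS to the *other* interactor. When both sides name the gene,
#' the partner is the interactor not containing the TSS; records where both
#' interactors contain the TSS are dropped and counted. Trans-chromosomal
#' partners are excluded and counted. Genes without an anchor are reported,
#' not fatal.
#'
#' @param records interaction data.frame (see [load_interactions()]).
#' @param genes character vector of symbols.
#' @param anchors data.frame from [read_anchors()].
#' @param label label for the set (e.g. `"up"`).
#' @inheritParams signed_distance
#' @return a `signed_distance_set` list: `label`, `distances` (numeric),
#'   `per_gene` (data.frame `gene`, `distance`), `missing_anchor`,
#'   `n_trans`, `n_dropped`.
#' @export
distance_set <- function(records, genes, anchors, label = "set",
                         mode = c("midpoint", "nearest"),
                         flip_sign = FALSE, strand_aware = TRUE) {
  mode <- match.arg(mode)
  genes <- unique(canonicalize_symbol(genes))
  ga <- canonicalize_symbol(ifelse(is.na(records$Agg_Gene_A) |
                                     records$Agg_Gene_A == "",
                                   "-", records$Agg_Gene_A))
  gb <- canonicalize_symbol(ifelse(is.na(records$Agg_Gene_B) |
                                     records$Agg_Gene_B == "",
                                   "-", records$Agg_Gene_B))
  missing_anchor <- setdiff(genes, anchors$symbol)
  n_trans <- 0L
  n_dropped <- 0L
  out_gene <- character(0)
  out_dist <- numeric(0)
  for (g in setdiff(genes, missing_anchor)) {
    anc <- anchors[match(g, anchors$symbol), , drop = FALSE]
    hit <- which(ga == g | gb == g)
    for (i in hit) {
      rec <- records[i, , drop = FALSE]
      in_a <- rec$InteractorAChr == anc$chrom &
        rec$InteractorAStart <= anc$tss & anc$tss < rec$InteractorAEnd
      in_b <- rec$InteractorBChr == anc$chrom &
        rec$InteractorBStart <= anc$tss & anc$tss < rec$InteractorBEnd
      side <- if (ga[i] == g && gb[i] == g) {
        # both sides name the gene: partner = the side not containing the TSS
        if (in_a && in_b) { n_dropped <- n_dropped + 1L; next }
        if (in_a) "B" else if (in_b) "A" else { n_dropped <- n_dropped + 1L; next }
      } else if (ga[i] == g) "B" else "A"
      pchrom <- rec[[paste0("Interactor", side, "Chr")]]
      if (pchrom != anc$chrom) { n_trans <- n_trans + 1L; next }
      d <- signed_distance_core(
        rec[[paste0("Interactor", side, "Start")]],
        rec[[paste0("Interactor", side, "End")]],
        anc$tss, anc$strand, mode = mode, flip_sign = flip_sign,
        strand_aware = strand_aware)
      out_gene <- c(out_gene, g)
      out_dist <- c(out_dist, d)
    }
  }
  structure(list(label = label, distances = out_dist,
                 per_gene = data.frame(gene = out_gene, distance = out_dist,
                                       stringsAsFactors = FALSE),
                 missing_anchor = missing_anchor,
                 n_trans = n_trans, n_dropped = n_dropped),
            class = "signed_distance_set")
}

#' @export
print.signed_distance_set <- function(x, ...) {
  cat("<signed_distance_set> ", x$label, ": ", length(x$distances),
      " distances", sep = "")
  if (x$n_trans) cat(";", x$n_trans, "trans excluded")
  if (length(x$missing_anchor)) {
    cat(";", length(x$missing_anchor), "gene(s) without anchor")
  }
  cat("\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test: `D` is the supremum of the absolute
#' difference of the two empirical CDFs (computed exactly over the pooled
#' sample points), and the p-value is the asymptotic Kolmogorov
#' approximation `p = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 t^2)` with
#' `t = sqrt(n1*n2/(n1+n2)) * D`.
#'
#' @param a,b numeric vectors or `signed_distance_set` objects (non-empty).
#' @return list with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(a, b) {
  if (inherits(a, "signed_distance_set")) a <- a$distances
  if (inherits(b, "signed_distance_set")) b <- b$distances
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  ecdf_a <- vapply(pooled, function(x) sum(a <= x), 0) / n1
  ecdf_b <- vapply(pooled, function(x) sum(b <= x), 0) / n2
  D <- max(abs(ecdf_a - ecdf_b))
  t <- sqrt(n1 * n2 / (n1 + n2)) * D
  p <- if (t < 1e-12) 1 else {
    k <- seq_len(101L)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  }
  list(statistic = D, p_value = p, n_a = n1, n_b = n2)
}

#' Empirical CDF table of a distance set
#'
#' Monotone nondecreasing from 0 to 1 over the sorted distances; convenient
#' for plotting or TSV export.
#'
#' @param x numeric vector or `signed_distance_set`.
#' @return data.frame `distance`, `ecdf`.
#' @export
ecdf_table <- function(x) {
  if (inherits(x, "signed_distance_set")) x <- x$distances
  x <- sort(as.numeric(x))
  if (!length(x)) stop("empty distance set", call. = FALSE)
  ux <- unique(x)
  data.frame(distance = ux,
             ecdf = vapply(ux, function(v) mean(x <= v), 0))
}
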