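# Gene catalogs: curated symbol sets with optional category annotations.
#
# The central catalog is the innatome -- the curated universe of innate
# immunity regulators (1376 genes as annotated here) -- whose members carry a
# subcellular-location class (5 levels) and a functional class (14 levels).
# Smaller panels (trained-immunity enzymes, heat-shock families, the
# oxidative/antioxidative "ROS regulatome", housekeeping genes) use the same
# container with their own annotation columns.

#' Closed vocabularies for catalog annotations
#'
#' Category labels accepted by [load_catalog()]: five subcellular-location
#' classes, fourteen functional classes, four trained-immunity pathways and
#' four heat-shock families.
#'
#' @name catalog-vocabularies
#' @export
LOCATION_CLASSES <- c("Cytoplasm", "Extracellular space", "Nucleus",
                      "Plasma membrane", "Other")

#' @rdname catalog-vocabularies
#' @export
FUNCTION_CLASSES <- c("Cytokine", "Enzyme", "G-protein-coupled receptor",
                      "Growth factor", "Ion channel", "Kinase",
                      "Ligand-dependent nuclear receptor", "Other",
                      "Peptidases", "Phosphatase", "Transcription regulator",
                      "Translation regulator", "Transmembrane receptor",
                      "Transporter")

#' @rdname catalog-vocabularies
#' @export
TRAINED_PATHWAYS <- c("glycolysis", "acetyl-CoA", "mevalonate", "epigenetic")

#' @rdname catalog-vocabularies
#' @export
HSP_FAMILIES <- c("HSP90", "DNAJ/HSP40", "small HSP", "HSP70")

#' The four housekeeping genes used for contrast quality control
#' @export
HOUSEKEEPING_GENES <- c("CHMP2A", "PSMB4", "ACTB", "GAPDH")

SPECIES_TAGS <- c("human", "mouse", "rat", "agnostic")

#' Canonicalize a gene symbol
#'
#' Gene symbols are matched across species by canonical form: upper-cased and
#' whitespace-stripped. Human symbols are conventionally all-caps and rodent
#' symbols Title-case ("Gpx3" vs "GPX3"); this package intersects lists across
#' species by canonical symbol only (no ortholog mapping -- a documented
#' limitation).
#'
#' @param symbol character vector of symbols.
#' @param species species tag, one of `"human"`, `"mouse"`, `"rat"`,
#'   `"agnostic"`; retained as metadata only, matching ignores it.
#' @return character vector of canonical symbols.
#' @export
#' @examples
#' canonicalize_symbol("Gpx3", "rat")    # "GPX3"
#' canonicalize_symbol(" GAPDH ", "human")
canonicalize_symbol <- function(symbol, species = "agnostic") {
  species <- match.arg(species, SPECIES_TAGS)
  if (length(symbol) == 0L) return(character(0))
  out <- toupper(trimws(as.character(symbol)))
  bad <- is.na(out) | out == ""
  if (any(bad)) {
    stop("empty or missing gene symbol at position(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  out
}

new_gene_catalog <- function(name, species, genes, annotations = NULL) {
  structure(list(name = name, species = species, genes = genes,
                 annotations = annotations),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", x$name, " (", x$species, "): ",
      length(x$genes), " genes", sep = "")
  if (!is.null(x$annotations)) {
    ann <- setdiff(names(x$annotations), "symbol")
    cat("; annotated:", paste(ann, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.gene_catalog <- function(x) length(x$genes)

#' Load a gene catalog from a TSV file
#'
#' The file must have a header with a `symbol` column; optional annotation
#' columns are `location_class`, `function_class`, `pathway`
#' (trained-immunity) and `family` (heat-shock), each validated against the
#' closed vocabularies in [catalog-vocabularies]. Duplicate symbols (after
#' canonicalization) are collapsed with a warning; annotation conflicts among
#' duplicates are an error.
#'
#' @param path path to a tab-separated catalog file.
#' @param species species tag (see [canonicalize_symbol()]).
#' @param name catalog name; defaults to the file name.
#' @return a `gene_catalog` object.
#' @export
load_catalog <- function(path, species = "agnostic",
                         name = sub("\\.[^.]*$", "", basename(path))) {
  species <- match.arg(species, SPECIES_TAGS)
  df <- read_tsv_strict(path)
  if (!"symbol" %in% names(df)) {
    stop("catalog file lacks a 'symbol' column: ", path, call. = FALSE)
  }
  if (nrow(df) == 0L) stop("catalog file is empty: ", path, call. = FALSE)
  as_gene_catalog(df, species = species, name = name)
}

# build/validate a catalog from an annotation data.frame
as_gene_catalog <- function(df, species = "agnostic", name = "catalog") {
  df$symbol <- canonicalize_symbol(df$symbol, species)
  vocab <- list(location_class = LOCATION_CLASSES,
                function_class = FUNCTION_CLASSES,
                pathway = TRAINED_PATHWAYS,
                family = HSP_FAMILIES)
  for (col in intersect(names(vocab), names(df))) {
    val <- df[[col]]
    known <- is.na(val) | val == "" | val %in% vocab[[col]]
    if (!all(known)) {
      i <- which(!known)[1L]
      stop(sprintf("unknown %s '%s' at row %d (symbol %s)",
                   col, val[i], i, df$symbol[i]), call. = FALSE)
    }
  }
  if (anyDuplicated(df$symbol)) {
    dups <- unique(df$symbol[duplicated(df$symbol)])
    warning(length(dups), " duplicate symbol(s) collapsed: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ..." else "", call. = FALSE)
    uniq <- !duplicated(df$symbol)
    # refuse silent loss of conflicting annotations
    ann_cols <- setdiff(names(df), "symbol")
    for (s in dups) {
      rows <- df[df$symbol == s, ann_cols, drop = FALSE]
      if (nrow(unique(rows)) > 1L) {
        stop("conflicting annotations for duplicated symbol ", s,
             call. = FALSE)
      }
    }
    df <- df[uniq, , drop = FALSE]
  }
  ann <- if (ncol(df) > 1L) {
    rownames(df) <- NULL
    df
  } else NULL
  new_gene_catalog(name, species, df$symbol, ann)
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_catalog()]; a write/read cycle round-trips exactly.
#'
#' @param catalog a `gene_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  df <- catalog$annotations %||% data.frame(symbol = catalog$genes,
                                            stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Category composition of a catalog subset
#'
#' Tabulates a subset of catalog genes (or the whole catalog) over one
#' annotation scheme, with percentages on the 0-100 scale rendered to
#' 2 decimals (half-up), mirroring the printed composition tables
#' (e.g. Cytoplasm 481 / 34.96\% of 1376).
#'
#' @param catalog a `gene_catalog` annotated under `scheme`.
#' @param subset character vector of catalog symbols, or `NULL` for all genes.
#' @param scheme `"location"` or `"function"`.
#' @param decimals decimal places for the rendered percentage.
#' @return a data.frame with columns `category`, `count`, `percent` (one row
#'   per vocabulary category, in vocabulary order) and attribute `total`.
#' @export
category_composition <- function(catalog, subset = NULL,
                                 scheme = c("location", "function"),
                                 decimals = 2) {
  stopifnot(inherits(catalog, "gene_catalog"))
  scheme <- match.arg(scheme)
  col <- paste0(scheme, "_class")
  levels <- if (scheme == "location") LOCATION_CLASSES else FUNCTION_CLASSES
  ann <- catalog$annotations
  if (is.null(ann) || !col %in% names(ann)) {
    stop("catalog '", catalog$name, "' has no ", col, " annotation",
         call. = FALSE)
  }
  if (is.null(subset)) {
    subset <- catalog$genes
  } else {
    subset <- canonicalize_symbol(subset, catalog$species)
    missing <- setdiff(subset, catalog$genes)
    if (length(missing)) {
      stop("subset members not in catalog: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
  }
  lab <- ann[[col]][match(subset, ann$symbol)]
  unannotated <- subset[is.na(lab) | lab == ""]
  if (length(unannotated)) {
    stop("subset members lack a ", col, " annotation: ",
         paste(utils::head(unannotated, 5L), collapse = ", "), call. = FALSE)
  }
  counts <- as.integer(table(factor(lab, levels = levels)))
  out <- data.frame(category = levels, count = counts,
                    percent = pct_render(counts, length(subset), decimals),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- length(subset)
  attr(out, "scheme") <- scheme
  out
}

#' Read a GMT pathway collection
#'
#' Standard tab-separated GMT: per line a pathway name, a description and the
#' member genes. Gene symbols are canonicalized.
#'
#' @param path path to a `.gmt` file.
#' @param species species tag used for symbol canonicalization.
#' @return named list of character vectors (unique canonical symbols); each
#'   element carries its description in attribute `"description"`.
#' @export
read_gmt <- function(path, species = "agnostic") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1L, 60L), call. = FALSE)
    }
    genes <- unique(canonicalize_symbol(parts[-(1:2)], species))
    attr(genes, "description") <- parts[2L]
    out[[parts[1L]]] <- genes
  }
  out
}
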