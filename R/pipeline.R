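# Pipeline orchestration: QC -> DEG calling -> innatome profiling ->
# enrichment -> mechanism concordance/ranking -> ROS classification ->
# CLRI analysis, emitting one structured JSON report plus TSV side-tables.
#
# Stages whose inputs are absent from the config are marked "skipped"; an
# error inside a stage aborts the run naming the stage. The report contains
# no timestamps, so identical config + inputs give byte-identical output.

#' Read a pipeline run configuration
#'
#' YAML (`.yml`/`.yaml`, requires the `yaml` package) or JSON. See
#' [run_pipeline()] for the recognized fields.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

resolve_catalog <- function(x, species = "agnostic") {
  if (inherits(x, "gene_catalog")) x
  else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    load_catalog(x, species = species)
  } else if (is.character(x)) {
    new_gene_catalog("inline", species, canonicalize_symbol(x, species))
  } else stop("cannot interpret catalog specification", call. = FALSE)
}

resolve_contrast <- function(x, default_species = "agnostic") {
  if (inherits(x, "contrast")) return(x)
  if (is.character(x)) x <- list(path = x)
  stopifnot(is.list(x))
  if (!is.null(x$contrast)) return(x$contrast)
  read_contrast(x$path,
                dataset_id = x$dataset_id %||% basename(x$path),
                species = x$species %||% default_species,
                log2_input = isTRUE(x$log2))
}

#' Run the full innatome-remodeling pipeline
#'
#' Config fields (R list, or a YAML/JSON file via [read_run_config()]):
#' \describe{
#'   \item{catalog}{innatome catalog: path, symbol vector or `gene_catalog`
#'     (required).}
#'   \item{contrasts}{list of contrast specs (`path`/`contrast`,
#'     `dataset_id`, `species`, `log2`) (required).}
#'   \item{threshold, qc_threshold}{fold-change cutoffs, both default 1.5.}
#'   \item{override_qc}{proceed on QC failure (default `FALSE`).}
#'   \item{panels}{named list of panel catalogs for panel scans (optional).}
#'   \item{gmt}{path to a GMT collection for enrichment of each DEG set
#'     within the catalog universe (optional).}
#'   \item{perturbations}{list of contrast specs each carrying a
#'     `mechanism` label, for concordance + ranking (optional).}
#'   \item{ros}{list with `nox2`/`nrf2` contrast specs; classifies each
#'     contrast's up- and down-sets (optional).}
#'   \item{interactions, anchors}{interaction TSV and BED6 anchor paths (or
#'     data.frames) for CLRI distances of each contrast's up/down sets,
#'     compared by KS (optional).}
#' }
#'
#' @param config named list or path to a config file.
#' @param out_dir output directory; created if needed. `NULL` suppresses all
#'   file output and just returns the report.
#' @return the report as a named list (invisibly writes `report.json` and
#'   TSV side-tables under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  threshold <- config$threshold %||% 1.5
  qc_threshold <- config$qc_threshold %||% 1.5
  if (threshold <= 1 || qc_threshold <= 1) {
    stop("thresholds must exceed 1", call. = FALSE)
  }
  report <- list(schema_version = "1.0",
                 parameters = list(threshold = threshold,
                                   qc_threshold = qc_threshold))
  stage <- function(name, enabled, fun) {
    if (!enabled) {
      return(list(status = "skipped",
                  reason = "required inputs absent from config"))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    c(list(status = "ok"), res)
  }

  if (is.null(config$catalog) || is.null(config$contrasts)) {
    stop("config must provide 'catalog' and 'contrasts'", call. = FALSE)
  }
  catalog <- resolve_catalog(config$catalog)
  contrasts <- lapply(config$contrasts, resolve_contrast)
  names(contrasts) <- vapply(contrasts, `[[`, "", "dataset_id")

  # --- QC + DEG calling -----------------------------------------------
  degs <- list()
  report$degs <- stage("degcall", TRUE, function() {
    per <- lapply(contrasts, function(ct) {
      ct <- with_qc(ct, qc_threshold = qc_threshold)
      deg <- call_degs(ct, catalog, threshold = threshold,
                       override_qc = isTRUE(config$override_qc))
      degs[[ct$dataset_id]] <<- deg
      list(dataset_id = ct$dataset_id,
           qc = list(pass = ct$qc$pass,
                     max_abs_fc = ct$qc$max_abs_fc,
                     values = as.list(ct$qc$values)),
           n_up = length(deg$up), n_down = length(deg$down),
           pct_up = percent_of_catalog(length(deg$up), deg$catalog_total),
           pct_down = percent_of_catalog(length(deg$down),
                                         deg$catalog_total),
           up = deg$up, down = deg$down)
    })
    list(catalog = catalog$name, catalog_size = length(catalog$genes),
         datasets = per)
  })

  # --- composition profiling ------------------------------------------
  has_comp <- !is.null(catalog$annotations) &&
    "location_class" %in% names(catalog$annotations)
  report$composition <- stage("profile", has_comp, function() {
    per <- lapply(degs, function(deg) {
      lapply(c(up = "up", down = "down"), function(dir) {
        genes <- deg[[dir]]
        if (!length(genes)) return(list(n = 0L))
        lapply(c(location = "location", `function` = "function"),
               function(sch) compare_composition(genes, catalog, sch))
      })
    })
    list(datasets = per)
  })

  # --- venn across datasets -------------------------------------------
  report$venn <- stage("venn", length(degs) >= 2L && length(degs) <= 5L,
                       function() {
    list(up = as.list(venn_partition(lapply(degs, `[[`, "up"))),
         down = as.list(venn_partition(lapply(degs, `[[`, "down"))))
  })

  # --- panel scans -----------------------------------------------------
  report$panels <- stage("panels", !is.null(config$panels), function() {
    res <- lapply(config$panels, function(p) {
      scan <- panel_scan(contrasts, resolve_catalog(p), threshold)
      list(panel_size = scan$panel_size,
           per_contrast = scan$per_contrast,
           pooled_up = scan$pooled_up, pooled_down = scan$pooled_down,
           ratio_down_over_up = scan$ratio_down_over_up,
           ratio_up_over_down = scan$ratio_up_over_down)
    })
    list(panels = res)
  })

  # --- enrichment ------------------------------------------------------
  report$enrichment <- stage("enrich", !is.null(config$gmt), function() {
    gmt <- if (is.character(config$gmt)) read_gmt(config$gmt)
           else config$gmt
    res <- lapply(degs, function(deg) {
      lapply(c(up = "up", down = "down"), function(dir) {
        genes <- deg[[dir]]
        if (!length(genes)) return(NULL)
        hypergeom_enrich(genes, gmt, catalog)
      })
    })
    list(datasets = res)
  })

  # --- mechanism concordance + ranking --------------------------------
  report$mechanisms <- stage("mechanisms",
                             !is.null(config$perturbations), function() {
    perts <- lapply(config$perturbations, resolve_contrast)
    grouping <- vapply(config$perturbations, function(p) {
      if (inherits(p, "contrast") || is.null(p$mechanism)) NA_character_
      else p$mechanism
    }, "")
    names(grouping) <- vapply(perts, `[[`, "", "dataset_id")
    if (anyNA(grouping)) {
      stop("every perturbation needs a 'mechanism' label")
    }
    refs <- unlist(lapply(degs, function(deg) {
      list(modulated_set(deg, "up"), modulated_set(deg, "down"))
    }), recursive = FALSE)
    refs <- refs[vapply(refs, function(r) length(r$genes) > 0L, TRUE)]
    if (!length(refs)) stop("no non-empty reference sets")
    cm <- concordance_matrix(refs, perts, threshold)
    list(cells = as.data.frame(cm),
         ranking = as.data.frame(rank_mechanisms(cm, grouping)))
  })

  # --- ROS classification ---------------------------------------------
  report$ros <- stage("rosclass", !is.null(config$ros), function() {
    nox2 <- lapply(config$ros$nox2 %||% list(), resolve_contrast)
    nrf2 <- lapply(config$ros$nrf2 %||% list(), resolve_contrast)
    res <- lapply(degs, function(deg) {
      lapply(c(up = "up", down = "down"), function(dir) {
        genes <- deg[[dir]]
        if (!length(genes)) return(NULL)
        cls <- classify_set(genes, nox2, nrf2, threshold)
        list(counts = as.list(cls$counts),
             percent = as.list(cls$percent),
             ros_related = cls$ros_related,
             assignments = cls$assignments)
      })
    })
    list(datasets = res)
  })

  # --- CLRI ------------------------------------------------------------
  has_clri <- !is.null(config$interactions) && !is.null(config$anchors)
  report$clri <- stage("clri", has_clri, function() {
    records <- if (is.character(config$interactions)) {
      load_interactions(config$interactions)
    } else config$interactions
    anchors <- if (is.character(config$anchors)) {
      read_anchors(config$anchors)
    } else config$anchors
    res <- lapply(degs, function(deg) {
      up <- distance_set(records, deg$up, anchors, label = "up")
      down <- distance_set(records, deg$down, anchors, label = "down")
      out <- list(n_up = length(up$distances),
                  n_down = length(down$distances),
                  n_trans = up$n_trans + down$n_trans)
      if (length(up$distances) && length(down$distances)) {
        ks <- ks_compare(up, down)
        out$ks <- list(statistic = ks$statistic, p_value = ks$p_value)
      }
      out$distances <- list(up = up$distances, down = down$distances)
      out
    })
    list(datasets = res)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", null = "null")
    for (id in names(degs)) {
      deg <- degs[[id]]
      write_tsv_plain(
        data.frame(symbol = c(deg$up, deg$down),
                   direction = rep(c("up", "down"),
                                   c(length(deg$up), length(deg$down))),
                   stringsAsFactors = FALSE),
        file.path(out_dir, paste0("degs_", id, ".tsv")))
    }
  }
  invisible(report)
}
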