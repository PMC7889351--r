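# Seeded synthetic-data generation with exported ground truth.
#
# Generators emulate every input class the pipeline consumes: an annotated
# innatome catalog with the published composition margins, probe-level
# expression contrasts with stable housekeeping genes and planted up/down
# genes, perturbation suites with planted concordance fractions, NOX2/Nrf2
# knockout panels with a planted four-group ROS structure, and interaction
# tables with planted signed distance distributions. All randomness flows
# from the `seed` argument; identical seeds give identical outputs.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic innatome catalog with the published composition margins
#'
#' 1376 synthetic symbols (`IG0001`...) annotated so that the marginal
#' counts over the five subcellular-location classes (481/151/405/86/253)
#' and the fourteen functional classes (53/232/22/21/8/113/6/459/54/22/229/
#' 10/88/59) match the published innatome composition table. The joint
#' location x function assignment is arbitrary (the source only reports
#' margins). Deterministic; no seed needed.
#'
#' @param species species tag (default `"agnostic"`).
#' @return an annotated `gene_catalog` of 1376 genes.
#' @export
gen_innatome_catalog <- function(species = "agnostic") {
  loc_counts <- c(481L, 151L, 405L, 86L, 253L)
  fun_counts <- c(53L, 232L, 22L, 21L, 8L, 113L, 6L, 459L, 54L, 22L,
                  229L, 10L, 88L, 59L)
  n <- sum(loc_counts)
  stopifnot(sum(fun_counts) == n)
  df <- data.frame(
    symbol = sprintf("IG%04d", seq_len(n)),
    location_class = rep(LOCATION_CLASSES, loc_counts),
    function_class = rep(FUNCTION_CLASSES, fun_counts),
    stringsAsFactors = FALSE)
  as_gene_catalog(df, species = species, name = "innatome_synthetic")
}

#' Synthetic gene panels (trained immunity, heat shock, ROS regulatome,
#' housekeeping)
#'
#' Panel sizes follow the curated panels: 102 trained-immunity enzymes over
#' four pathways, 82 heat-shock proteins in four families (5 HSP90,
#' 49 DNAJ/HSP40, 11 small HSP, 17 HSP70), 84 oxidative/antioxidative genes,
#' and the 4 housekeeping genes. Trained-immunity and ROS panels draw their
#' members from `catalog` (panels are subsets of the innatome here so that
#' panel scans have a defined universe); heat-shock and housekeeping panels
#' use their own symbols.
#'
#' @param kind one of `"trained"`, `"hsp"`, `"ros"`, `"housekeeping"`.
#' @param catalog a `gene_catalog` to draw members from (trained/ros kinds).
#' @param seed integer seed for member sampling (trained/ros kinds).
#' @return a `gene_catalog`.
#' @export
gen_panel_catalog <- function(kind = c("trained", "hsp", "ros",
                                       "housekeeping"),
                              catalog = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "housekeeping") {
    return(new_gene_catalog("housekeeping", "agnostic", HOUSEKEEPING_GENES))
  }
  if (kind == "hsp") {
    fam <- rep(HSP_FAMILIES, c(5L, 49L, 11L, 17L))
    df <- data.frame(symbol = sprintf("HSP%03d", seq_along(fam)),
                     family = fam, stringsAsFactors = FALSE)
    return(as_gene_catalog(df, name = "heat_shock_synthetic"))
  }
  stopifnot(inherits(catalog, "gene_catalog"))
  n <- if (kind == "trained") 102L else 84L
  members <- with_seed(seed, sort(sample(catalog$genes, n)))
  df <- data.frame(symbol = members, stringsAsFactors = FALSE)
  if (kind == "trained") {
    # pathway composition chosen once: glycolysis-dominated, mirroring the
    # enzyme families the trained-immunity literature enumerates
    df$pathway <- with_seed(seed + 1L, sample(rep(TRAINED_PATHWAYS,
                                                  c(35L, 10L, 15L, 42L))))
    name <- "trained_immunity_synthetic"
  } else {
    name <- "ros_regulatome_synthetic"
  }
  as_gene_catalog(df, species = catalog$species, name = name)
}

#' Synthetic expression contrast with planted truth
#'
#' Generates a probe-level expression table over the catalog genes plus the
#' four housekeeping genes, builds the `contrast`, and exports the planted
#' truth. Baseline linear intensities are log-normal (meanlog 7, sdlog 1,
#' plausible microarray scale; irrelevant to ratios). Planted up genes get a
#' treatment/control ratio of `effect_fc`, down genes `1/effect_fc`, all
#' others 1; multiplicative log-normal noise with sdlog `noise_sd` is
#' applied to the treatment value (so the signed-fc log-ratio has sd
#' `noise_sd`). Housekeeping rows are planted with |fc| <= 1.28 (the
#' observed regime) and no added noise, so generated contrasts always pass
#' QC at threshold 1.5 by construction.
#'
#' @param seed integer seed.
#' @param catalog `gene_catalog` or character vector of symbols.
#' @param n_up,n_down numbers of planted up/down genes (ignored when
#'   `up_genes`/`down_genes` given).
#' @param up_genes,down_genes explicit planted sets (must be disjoint
#'   members of the catalog).
#' @param effect_fc planted fold-change magnitude (default 2).
#' @param noise_sd sdlog of multiplicative noise on the ratio (default 0).
#' @param probes_per_gene probes per gene (default 1).
#' @param dataset_id,species contrast metadata.
#' @param include_housekeeping plant the four housekeeping genes
#'   (default `TRUE`).
#' @return list with `contrast` (a QC-annotated `contrast`) and `truth`
#'   (list `up`, `down`, `housekeeping_fc`, `effect_fc`, `noise_sd`).
#' @export
gen_expression <- function(seed, catalog, n_up = 77L, n_down = 39L,
                           up_genes = NULL, down_genes = NULL,
                           effect_fc = 2, noise_sd = 0,
                           probes_per_gene = 1L,
                           dataset_id = "synthetic_contrast",
                           species = "agnostic",
                           include_housekeeping = TRUE) {
  genes <- if (inherits(catalog, "gene_catalog")) catalog$genes
           else canonicalize_symbol(catalog)
  stopifnot(effect_fc > 1, noise_sd >= 0, probes_per_gene >= 1L)
  with_seed(seed, {
    if (is.null(up_genes) || is.null(down_genes)) {
      if (n_up + n_down > length(genes)) {
        stop("planted fractions exceed the catalog size", call. = FALSE)
      }
      planted <- sample(genes, n_up + n_down)
      up_genes <- sort(planted[seq_len(n_up)])
      down_genes <- sort(planted[n_up + seq_len(n_down)])
    } else {
      up_genes <- sort(canonicalize_symbol(up_genes))
      down_genes <- sort(canonicalize_symbol(down_genes))
      stopifnot(all(c(up_genes, down_genes) %in% genes),
                length(intersect(up_genes, down_genes)) == 0L)
    }
    ratio <- rep(1, length(genes))
    ratio[genes %in% up_genes] <- effect_fc
    ratio[genes %in% down_genes] <- 1 / effect_fc
    sym <- rep(genes, each = probes_per_gene)
    rat <- rep(ratio, each = probes_per_gene)
    control <- stats::rlnorm(length(sym), meanlog = 7, sdlog = 1)
    treat <- control * rat * exp(stats::rnorm(length(sym), 0, noise_sd))
    hk_fc <- NULL
    if (include_housekeeping) {
      # |fc| in the narrow observed band, sign at random, no extra noise
      mag <- stats::runif(4L, 1.0, 1.28)
      sgn <- sample(c(1, -1), 4L, replace = TRUE)
      hk_fc <- stats::setNames(ifelse(sgn > 0, mag, -mag),
                               HOUSEKEEPING_GENES)
      hk_control <- stats::rlnorm(4L, meanlog = 7, sdlog = 1)
      hk_treat <- hk_control * ifelse(sgn > 0, mag, 1 / mag)
      sym <- c(sym, HOUSEKEEPING_GENES)
      control <- c(control, hk_control)
      treat <- c(treat, hk_treat)
    }
    df <- data.frame(
      feature_id = paste0(sym, "_p",
                          stats::ave(seq_along(sym), sym, FUN = seq_along)),
      symbol = sym, treat_mean = treat, control_mean = control,
      stringsAsFactors = FALSE)
    ct <- with_qc(as_contrast(df, dataset_id = dataset_id,
                              species = species))
    list(contrast = ct,
         truth = list(up = up_genes, down = down_genes,
                      housekeeping_fc = hk_fc, effect_fc = effect_fc,
                      noise_sd = noise_sd))
  })
}

#' Synthetic perturbation suite with planted concordance fractions
#'
#' For each mechanism, generates one or more perturbation contrasts over the
#' reference genes in which a planted fraction of reference genes responds
#' (split between up and down by `up_share`); the remaining reference genes
#' sit at ratio 1. Default fractions plant the intended mechanism ordering
#' ros > checkpoint > cytokine > shear_heat.
#'
#' @param seed integer seed.
#' @param reference a `modulated_set` or character vector of genes.
#' @param mechanisms named numeric vector of responsive fractions in
#'   `[0, 1]` per mechanism.
#' @param datasets_per_mechanism contrasts generated per mechanism.
#' @param up_share fraction of responsive genes planted up (default 0.5).
#' @inheritParams gen_expression
#' @return list with `contrasts` (named list), `grouping` (dataset ->
#'   mechanism), `truth` (per dataset: `up`, `down`, `fraction`).
#' @export
gen_perturbation_suite <- function(seed, reference,
                                   mechanisms = c(ros = 0.65,
                                                  checkpoint = 0.30,
                                                  cytokine = 0.20,
                                                  shear_heat = 0.10),
                                   datasets_per_mechanism = 1L,
                                   up_share = 0.5, effect_fc = 2,
                                   noise_sd = 0, species = "agnostic") {
  genes <- if (inherits(reference, "modulated_set")) reference$genes
           else canonicalize_symbol(reference)
  if (any(mechanisms < 0 | mechanisms > 1)) {
    stop("mechanism fractions must lie in [0, 1]", call. = FALSE)
  }
  contrasts <- list()
  grouping <- character(0)
  truth <- list()
  if (length(mechanisms) == 0L) {
    return(list(contrasts = contrasts, grouping = grouping, truth = truth))
  }
  i <- 0L
  for (m in names(mechanisms)) {
    for (d in seq_len(datasets_per_mechanism)) {
      i <- i + 1L
      id <- paste0(m, "_", d)
      n_resp <- round(mechanisms[[m]] * length(genes))
      picked <- with_seed(seed + i, sample(genes, n_resp))
      n_up <- round(up_share * n_resp)
      sim <- gen_expression(seed + 1000L + i, genes,
                            up_genes = picked[seq_len(n_up)],
                            down_genes = picked[n_up + seq_len(n_resp - n_up)],
                            effect_fc = effect_fc, noise_sd = noise_sd,
                            dataset_id = id, species = species,
                            include_housekeeping = TRUE)
      contrasts[[id]] <- sim$contrast
      grouping[id] <- m
      truth[[id]] <- list(up = sim$truth$up, down = sim$truth$down,
                          fraction = mechanisms[[m]])
    }
  }
  list(contrasts = contrasts, grouping = grouping, truth = truth)
}

#' Synthetic NOX2-KO / Nrf2-KO panels with planted ROS groups
#'
#' Assigns each gene one of the four ROS-dependency groups (default counts
#' 40/26/4/38 over a 108-gene set, the bone-marrow regime) and builds one
#' NOX2-KO and one Nrf2-KO contrast realizing them: promoted genes are down
#' in NOX2-KO and up in Nrf2-KO, suppressed genes the mirror image,
#' uncertain genes down in both (conflicting evidence), independent genes
#' unchanged in both.
#'
#' @param seed integer seed.
#' @param genes character vector of symbols to classify.
#' @param groups named integer vector (`promoted`, `suppressed`,
#'   `uncertain`, `independent`) summing to `length(genes)`.
#' @inheritParams gen_expression
#' @return list with `nox2` and `nrf2` (each a `contrast`) and `truth`
#'   (data.frame `gene`, `group`).
#' @export
gen_ros_ko_panels <- function(seed, genes,
                              groups = c(promoted = 40L, suppressed = 26L,
                                         uncertain = 4L, independent = 38L),
                              effect_fc = 2, noise_sd = 0,
                              species = "agnostic") {
  genes <- unique(canonicalize_symbol(genes))
  stopifnot(setequal(names(groups), ROS_GROUPS))
  if (sum(groups) != length(genes)) {
    stop("group counts must sum to the number of genes", call. = FALSE)
  }
  assign <- with_seed(seed,
                      sample(rep(ROS_GROUPS[match(names(groups),
                                                  ROS_GROUPS)], groups)))
  promoted <- genes[assign == "promoted"]
  suppressed <- genes[assign == "suppressed"]
  uncertain <- genes[assign == "uncertain"]
  nox2 <- gen_expression(seed + 1L, genes,
                         up_genes = suppressed,
                         down_genes = c(promoted, uncertain),
                         effect_fc = effect_fc, noise_sd = noise_sd,
                         dataset_id = "nox2_ko_synthetic",
                         species = species)$contrast
  nrf2 <- gen_expression(seed + 2L, genes,
                         up_genes = promoted,
                         down_genes = c(suppressed, uncertain),
                         effect_fc = effect_fc, noise_sd = noise_sd,
                         dataset_id = "nrf2_ko_synthetic",
                         species = species)$contrast
  list(nox2 = nox2, nrf2 = nrf2,
       truth = data.frame(gene = genes, group = assign,
                          stringsAsFactors = FALSE))
}

#' Synthetic interaction table and anchors with planted distances
#'
#' Places the genes of two sets on one chromosome (TSS base 6e7, 1e5
#' spacing, alternating strand) and draws one cis interaction partner per
#' requested record with log-uniform distance magnitude in
#' `[1e4, 5e7]` base pairs -- the band where upstream interaction sites
#' concentrate in the source analysis. Up-set partners fall downstream
#' (positive) with probability `up_downstream_bias`; down-set partners fall
#' upstream (negative) with probability `down_upstream_bias`. A few trans
#' and malformed rows are injected for parser tests and flagged in the
#' truth table. The emitted table uses 1-based inclusive coordinates (the
#' on-disk convention); truth distances are exact integers recovered by
#' [distance_set()] on the loaded file.
#'
#' @param seed integer seed.
#' @param up_genes,down_genes symbols of the two gene sets.
#' @param n_per_set interaction records per set (default 98, the analyzed
#'   site count).
#' @param mag_range distance magnitude range in bp (default `c(1e4, 5e7)`).
#' @param up_downstream_bias,down_upstream_bias sign biases (default 0.85).
#' @param n_trans,n_malformed injected bad rows (defaults 2 and 2).
#' @param partner_width partner interval width in bp (even; default 2000).
#' @param dir optional directory; when given, writes `interactions.tsv` and
#'   `anchors.bed` there and records the paths in the result.
#' @return list with `records_source` (1-based table incl. injected rows),
#'   `anchors`, `truth` (list `up`, `down`: data.frames `gene`, `distance`;
#'   `n_trans`, `n_malformed`), and optionally `paths`.
#' @export
gen_interactions <- function(seed, up_genes, down_genes, n_per_set = 98L,
                             mag_range = c(1e4, 5e7),
                             up_downstream_bias = 0.85,
                             down_upstream_bias = 0.85,
                             n_trans = 2L, n_malformed = 2L,
                             partner_width = 2000L, dir = NULL) {
  if (n_per_set < 0L) stop("n_per_set must be >= 0", call. = FALSE)
  up_genes <- unique(canonicalize_symbol(up_genes))
  down_genes <- unique(canonicalize_symbol(down_genes))
  all_genes <- c(up_genes, down_genes)
  stopifnot(length(all_genes) >= 1L, partner_width %% 2L == 0L)
  anchors <- data.frame(
    symbol = all_genes, chrom = "chr1",
    tss = 6e7 + (seq_along(all_genes) - 1L) * 1e5,
    strand = rep(c("+", "-"), length.out = length(all_genes)),
    stringsAsFactors = FALSE)
  half <- partner_width / 2
  make_set <- function(genes, pos_bias, sub_seed) {
    if (length(genes) == 0L || n_per_set == 0L) {
      return(list(rows = NULL,
                  truth = data.frame(gene = character(0),
                                     distance = numeric(0))))
    }
    with_seed(sub_seed, {
      g <- sample(genes, n_per_set, replace = TRUE)
      mag <- round(10^stats::runif(n_per_set, log10(mag_range[1L]),
                                   log10(mag_range[2L])))
      sgn <- ifelse(stats::runif(n_per_set) < pos_bias, 1, -1)
      d <- sgn * mag  # signed distance in gene orientation
      idx <- match(g, anchors$symbol)
      tss <- anchors$tss[idx]
      strand <- anchors$strand[idx]
      g_off <- ifelse(strand == "-", -d, d)   # genomic offset
      mid <- tss + g_off
      rows <- data.frame(
        InteractorAChr = "chr1",
        InteractorAStart = tss - 500, InteractorAEnd = tss + 500,
        InteractorBChr = "chr1",
        InteractorBStart = mid - half, InteractorBEnd = mid + half,
        Agg_Gene_A = g, Agg_Gene_B = "",
        Detection_Method = "Hi-C", Cell_Tissue = "synthetic",
        stringsAsFactors = FALSE)
      list(rows = rows,
           truth = data.frame(gene = g, distance = d,
                              stringsAsFactors = FALSE))
    })
  }
  up <- make_set(up_genes, up_downstream_bias, seed + 1L)
  down <- make_set(down_genes, 1 - down_upstream_bias, seed + 2L)
  records <- rbind(up$rows, down$rows)
  if (n_trans > 0L && length(all_genes) > 0L && !is.null(records)) {
    trans <- records[rep(1L, n_trans), , drop = FALSE]
    trans$InteractorBChr <- "chr2"
    records <- rbind(records, trans)
  }
  if (n_malformed > 0L && !is.null(records)) {
    bad <- records[rep(1L, n_malformed), , drop = FALSE]
    bad$InteractorBEnd <- bad$InteractorBStart - 10  # empty interval
    records <- rbind(records, bad)
  }
  # convert internal 0-based half-open to 1-based inclusive on-disk form
  src <- records
  if (!is.null(src)) {
    src$InteractorAStart <- src$InteractorAStart + 1
    src$InteractorBStart <- src$InteractorBStart + 1
  }
  out <- list(records_source = src, anchors = anchors,
              truth = list(up = up$truth, down = down$truth,
                           n_trans = if (is.null(records)) 0L else n_trans,
                           n_malformed = if (is.null(records)) 0L
                                         else n_malformed))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(interactions = file.path(dir, "interactions.tsv"),
                  anchors = file.path(dir, "anchors.bed"))
    write_tsv_plain(src, paths$interactions)
    write_anchors(anchors, paths$anchors)
    out$paths <- paths
  }
  out
}
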