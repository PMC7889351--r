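Package: innatomeMiner
Title: Innate-Immunity Gene ('Innatome') Remodeling Analysis for
    Treatment-vs-Control Expression Contrasts
Version: 0.1.0
Authors@R:
    person("Innatome", "Miner Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to profile how a treatment remodels the innate-immunity
    gene repertoire ('innatome') from microarray-style expression contrasts.
    Calls up/down-regulated genes by signed fold change with housekeeping-gene
    quality control, profiles the calls against curated gene catalogs
    (subcellular location and functional composition, trained-immunity,
    heat-shock and oxidative/antioxidative panels), attributes modulated
    genes to candidate mechanisms via cross-dataset directional concordance
    and a rule-based reactive-oxygen-species dependency classifier, performs
    hypergeometric gene-set enrichment against GMT collections, and
    characterizes chromatin long-range interaction distances relative to
    transcription start sites with two-sample Kolmogorov-Smirnov comparison.
    Includes seeded synthetic-data generators with exported ground truth for
    every input class, and a pipeline orchestrator producing a structured
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
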