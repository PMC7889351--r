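---
title: "Methods: profiling innatome remodeling from expression contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling innatome remodeling from expression contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innatomeMiner)
```

# The problem and the model

Low-intensity ultrasound and similar physical therapies remodel innate
immunity differently in cancer and noncancer cells. The analysis this
package implements treats that remodeling question as a chain of simple,
auditable statistics over one curated gene universe — the *innatome*, the
set of annotated innate-immunity regulators (1376 genes in the composition
used here, each carrying one of 5 subcellular-location classes and one of
14 functional classes):

1. **Differential calling.** A contrast is one treatment-vs-control
   comparison summarized per gene by a signed fold change with magnitude
   ≥ 1: `t/c` when treatment is higher, `-(c/t)` otherwise. A gene is
   up-/down-regulated when `|fc| >= 1.5`. There is deliberately no
   p-value or moderated-t gate — the upstream studies define modulation by
   fold change alone, and significance columns in inputs are ignored.
2. **Profiling.** Called sets are summarized as percentages of the
   catalog, compared in category composition against the whole catalog,
   intersected across cell types (Venn partitions), and scanned against
   focused panels (102 trained-immunity enzymes, 82 heat-shock proteins in
   four families, 84 oxidative/antioxidative genes).
3. **Attribution.** Reference DEG sets are followed into perturbation
   datasets; the fraction responding in at least one dataset of a
   mechanism ranks candidate mechanisms. A rule-based classifier assigns
   ROS dependency from NOX2-KO and Nrf2-KO response directions.
4. **Chromatin context.** Long-range interaction partners of modulated
   genes are measured as signed distances from the TSS and up- vs
   down-set distributions compared by the two-sample Kolmogorov–Smirnov
   test.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` | 1.5 | fold | The defining cutoff of the source analyses. The boundary is *included*: "more than 1.5-fold" is ambiguous in prose, and inclusion makes the rule `|fc| >= t`, monotone and exactly testable. Configurable. |
| `qc_threshold` | 1.5 | fold | Housekeeping genes (CHMP2A, PSMB4, ACTB, GAPDH) must stay strictly below it. The observed housekeeping range in the source datasets was −1.27…1.28, far inside the bound; 1.5 ties QC to the DEG scale. |
| `alpha` | 0.05 | — | Per-category flagging level for composition comparisons, uncorrected by default (matching per-category asterisks in the source tables); BH optional. |
| `min_size` | 3 | genes | Pathways smaller than this after universe intersection are skipped in enrichment — their hypergeometric tails are degenerate. |
| `measured_denominator` | FALSE | — | Concordance percentages divide by the full reference size (headline style, "of 77"), not by the measured subset; the option flips that. |

# Conventions and tie-breaks

* **Symbols.** Matching across species is by canonical (upper-cased,
  trimmed) symbol only; no ortholog mapping. That is how the source lists
  were intersected and is a documented limitation — paralog collisions and
  genuine cross-species differences are invisible to it.
* **Probe collapse.** A gene keeps its probe of largest |fc|; a tie in
  magnitude with opposite signs is undecidable and the gene is excluded as
  *ambiguous* (reported, never silently dropped into either set).
* **QC failure** blocks calling with a typed error carrying the QC report;
  an explicit override proceeds with a warning.
* **Composition background** is the whole catalog *including* the subset,
  mirroring how the source tables juxtapose whole-innatome columns with
  DEG columns. Fisher's exact test (two-sided) was chosen over a
  two-proportion z-test because several categories are tiny (6 genes).
* **Percent rendering** is round-half-up: 2 decimals in composition
  tables, 1 decimal in headline fractions — matching the two printed
  styles. Base R's banker's rounding would disagree exactly at ties.
* **ROS rule.** The published definition reads as an AND over both KO
  types, but the existence of an "uncertain" class implies single-sided
  evidence also counts. Default mode `"any"`: promoted-evidence =
  down-in-NOX2-KO or up-in-Nrf2-KO; suppressed-evidence the mirror; both
  kinds ⇒ uncertain; neither ⇒ independent. A `"strict"` mode requiring
  concordant evidence from both KO types is provided; single-sided
  evidence then falls back to uncertain.
* **CLRI sign.** The two method descriptions in the source disagree on
  sign; the adopted convention (negative = partner upstream of the
  promoter in gene orientation) is the one consistent with the reported
  upstream concentration between −5×10⁷ and −10⁴ bp. `flip_sign` covers
  the other reading. Distances are strand-aware by default;
  `strand_aware = FALSE` reproduces a raw-coordinate computation.
  Partners are midpoints by default (`mode = "nearest"` available);
  coordinates are 0-based half-open internally, converted from 1-based
  inclusive interaction files and from 0-based BED anchors.
* **KS test.** D is computed by an exact sweep over pooled sample points;
  the p-value is the asymptotic Kolmogorov series (the same approximation
  `stats::ks.test(exact = FALSE)` uses). Signed distances from real
  interaction tables contain ties; the asymptotic p is then conservative,
  which is acceptable at the p < 0.001 level the analysis uses.

# What the synthetic generators emulate — and what they do not

The upstream study's gene lists are not published, so dataset-level DEG
identities cannot be reproduced; all recovery claims are made against
seeded generators whose ground truth is exported.

* `gen_innatome_catalog()` reproduces the published composition *margins*
  exactly; the joint location×function table is arbitrary because only
  margins are printed.
* `gen_expression()` plants DEGs at a chosen signed fold change on a
  log-normal baseline (meanlog 7, sdlog 1 — plausible linear microarray
  intensities, irrelevant to ratios). Noise is multiplicative log-normal
  applied to the treatment value, so the log-ratio has standard deviation
  `noise_sd`: the single-draw reading of "log-normal noise on linear
  expression", fixed a priori (putting independent noise on both group
  means would double the ratio variance and contradict the stated
  recovery regime). Housekeeping rows are planted inside the observed
  ±1.28 band with no extra noise, so generated contrasts pass QC by
  construction — that makes "generated QC always passes" a contract, not
  a statistical event.
* `gen_perturbation_suite()` plants per-mechanism responsive fractions
  (defaults 0.65/0.30/0.20/0.10 for ros/checkpoint/cytokine/shear_heat,
  the intended ranking); `gen_ros_ko_panels()` plants the four-group
  partition (default 40/26/4/38 of 108, the bone-marrow up-set regime).
* `gen_interactions()` places genes on one synthetic chromosome and draws
  partner distances log-uniform in 10⁴…5×10⁷ bp with a 0.85 sign bias
  (up-set downstream, down-set upstream — the reported pattern), plus a
  few trans and malformed rows flagged in the truth table so parser
  counters are assertable.

None of this simulates probe-level array physics, normalization
artifacts, correlated genes, or real genome annotation. A green recovery
test therefore establishes that the *pipeline arithmetic* is correct under
the stated world — not that the biological conclusions of any particular
dataset re-analysis would reproduce.

# Numerical and design notes

* The catalog of record is the 1376-gene annotated table (the upstream
  source mentions a 1467-gene list of which 1376 were recognized by the
  annotation tool); the loader accepts any size.
* Two printed figures in the source are internally inconsistent with
  their own counts (108/1376 rendered as 7.9% instead of 7.8%; ROS-panel
  percentages quoted against a denominator of 84 that matches 81). The
  package always computes from counts; tests assert the arithmetic, not
  the typos.
* Fisher's exact test is conservative on discrete 2×2 tables: under
  uniform null subsets of size 100 from the 1376-gene catalog, its exact
  per-category flag rate (obtainable by enumerating the hypergeometric
  null) ranges from 0.006 (6-gene category) to 0.047 — never the nominal
  0.05. The type-I property test therefore validates the Monte-Carlo flag
  rate against that enumerated exact rate, and separately that no
  category is anticonservative.
* Pooled panel counts across cell types count *unique* genes (a panel
  gene responding in two cell types is one gene), which is how the pooled
  "12 of 102" style figures combine per-cell-type counts.
* All generator randomness flows from the single `seed` argument;
  `with_seed()` isolates the RNG so generators never perturb the caller's
  stream. Pipeline reports contain no timestamps and serialize with fixed
  ordering, so reruns are byte-identical.

# Known limitations

* Symbol-level cross-species matching (above).
* No array normalization, batch correction, or moderated statistics —
  inputs are assumed preprocessed to comparable linear-scale group means
  (`log2_input` converts log2 matrices).
* The enrichment module is a generic hypergeometric stand-in for the
  commercial pathway tool used upstream; pathway names and p-values from
  that tool are out of scope.
* Concordance is descriptive binning, not causal inference; knockout
  contrasts are interpreted with the orientation given.
* CLRI analysis ignores interaction confidence/frequency and reduces
  partners to points.
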