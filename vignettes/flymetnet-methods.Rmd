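---
title: "Methods: metabolic networks, differential metabolomics, and feeding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic networks, differential metabolomics, and feeding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymetnet)
```

flymetnet reconstructs, as a file-backed library, an analysis stack for
*Drosophila* nutritional metabolomics: a compound–reaction–enzyme–gene
pathway database, four derived network-graph types with multi-omics overlay
attributes, hypergeometric pathway over-representation, a complete
metabolomics differential-statistics pipeline, and feeding-bout analytics
for 5 Hz fly-to-liquid-food interaction (FLIC) recordings. This vignette
documents the models, the parameters that matter, the numerical conventions,
and what the synthetic-data generators do and do not establish.

## The database and the four graph types

The database holds five entity classes — compounds, reactions, enzymes,
genes, pathways — with cross-references in both directions (a reaction lists
its enzymes; an enzyme lists its reactions; the loader unions both).
Referential integrity is deliberately *reported*, not enforced:
`validate_db()` returns dangling references as data so that partial database
builds remain usable. Two structural rules are hard errors at construction:
duplicated ids, and a compound appearing on both sides of one reaction. The
latter would create a self-loop in a compound network, which the edge
semantics (an edge is a substrate-to-product conversion) cannot represent.

Four graph types are derived from a reaction set:

* **CREG** — compounds, reactions, enzymes, and genes as typed nodes.
  Substrate→reaction and reaction→product edges are directed; catalysis
  (reaction—enzyme) and encoding (enzyme—gene) edges are undirected. Nodes of
  the same kind are never connected.
* **CR** — CREG without enzyme and gene nodes.
* **CG** — the compound–gene projection: an undirected compound—gene edge
  wherever a compound—reaction—enzyme—gene path exists. `creg_to_cg()` and a
  direct CG build are required to agree exactly, and the test suite checks
  this exhaustively over every seed set of up to three compounds in the toy
  database.
* **C** — compounds only, one edge per (substrate, product, reaction)
  triple, annotated with the generating reaction. A reversible reaction
  yields a single *undirected* edge rather than two directed ones, so
  edge-count statistics are not inflated. Whether the original tool
  connected all substrate×product pairs or curated main-compound pairs is
  not published; all-pairs is implemented.

Query expansion is exactly one step — seed compounds and genes pull in their
incident reactions, and the graph is the full closure of those reactions.
No iterative neighborhood growth is performed; local one-step networks are
what the published figures show. No currency-metabolite (water, ATP)
exclusion is applied by default, since the original method describes none;
`extract_subnetwork()` can remove any node set.

Nodes and edges are always held and serialized in lexicographic order, so
builds and exports are deterministic byte-for-byte.

## Overlay encoding

`attach_omics()` matches differential tables onto compound and gene nodes
through the identifier resolver (id, then case-insensitive name, then
synonym, then cross-reference value; ambiguity is reported, never guessed).
`style_nodes()` derives the categorical display encoding: compounds are
hexagons (red measured / salmon unmeasured), genes circles (blue / light
blue), enzymes green squares, reactions gray diamonds. Node size is

  size = base × (1 + gain × |log2FC|), clipped to [base, 4 × base]

with defaults base = 30 display units and gain = 0.5. The published figures
state only that size "reflects" the change; a linear gain with clipping was
chosen because it is monotone, and — with the direction of change carried as
its own attribute — invertible from exports. Significance outlines are green
iff the node is measured and q is below the threshold for its kind:
0.1 for metabolites (the Welch/FDR convention used throughout the study) and
0.05 for genes (the Wald/FDR convention of the RNA-seq analysis). Both are
parameters.

## Pathway over-representation

`hypergeom_upper_tail(k, K, n, N)` is the exact one-sided
P[X ≥ k], X ~ Hypergeometric(N, K, n), computed as a log-sum-exp over point
masses so that very small tails are stable. `enrich_pathways()` intersects
each pathway with the measurement universe before counting, tests only
pathways with at least one in-universe member, and adjusts with
Benjamini–Hochberg (the FDR procedure is unnamed in the source study; BH is
the platform default everywhere else in the pipeline, so it is used here
too). The universe is a required argument and should be the set of
*measured* compounds — the conservative convention — rather than the whole
database; whether the original analysis used measured compounds or the full
external pathway-set universe is not published. Only over-representation is
tested; the study reports no depletion tests.
`select_loading_quartiles()` feeds the selection: compounds at or above the
75th / at or below the 25th percentile of one component's loadings
(percentiles by linear interpolation).

## The metabolomics pipeline

The stage order is fixed and enforced through a scale flag on the table:

1. `filter_missing()` — a compound is removed when its missing fraction
   exceeds 50% in **every** condition group. The source method's phrasing
   ("more than 50% missing values for each condition") is ambiguous between
   this reading and removal when *any* group exceeds the threshold; the
   all-groups default keeps compounds reliably detected in one state (a
   fasted-only metabolite is biology, not noise), and `mode = "any-group"`
   provides the stricter alternative.
2. `impute_half_min()` — each missing cell becomes half of the feature's
   minimum observed value across all samples (per-feature, not global, not
   per-group, matching the documented behavior of the analysis platform the
   study used).
3. `compute_rsd()` — precision QC on the imputed raw values: per feature and
   group, RSD = sample SD / mean; group medians across features.
4. `range_scale()` — x′ = (x − mean) / (max − min) per feature; constant
   features are zeroed with a warning.
5. Tests and projections on the scaled table: `welch_de()` (Welch t,
   Welch–Satterthwaite df, two-sided p, BH q; the statistic is affine
   invariant, so scaled and raw values give identical p-values),
   `anova_de()` (one-way fixed effects, for ≥ 3 groups), `run_pca()`
   (covariance PCA of samples; per-condition 95% ellipses from the group
   score covariance and the χ²(2) 0.95 quantile), and `ward_cluster()`
   (Ward's criterion on unsquared Euclidean distances, `hclust` method
   `ward.D2`; items are pre-sorted by id so leaf order is reproducible).

Fold changes are always computed on the imputed raw values, which the scaled
table carries along — range-scaled values can be negative, so a ratio there
is meaningless. Degenerate Welch cases are conventions, not errors: both
groups zero-variance with equal means gives p = 1; with unequal means p = 0
plus a warning. The "ANOVA FDR > 0.1" phrasing in the source study's results
is treated as a typo for < 0.1; the threshold is a parameter either way.

## FLIC feeding analytics

An *interaction* is a sample strictly above the signal threshold (default
40 at 5 Hz; the strict inequality is a documented choice — the boundary
behavior is unpublished and the parameter is exposed). An *event* (bout) is
a maximal run of at least 5 consecutive interactions; a run still above
threshold at the final sample is censored, because the event did not
conclude within the recording. Runs separated by even one below-threshold
sample are distinct — no gap-bridging. Summaries follow the study's units
and exclusions: event duration in seconds; inter-event interval in minutes,
averaging only the gaps between consecutive events and defined only for
flies with ≥ 2 events; latency in minutes to the *first interaction* (not
the first event); zero-interaction flies flagged as non-eaters.

Group statistics use the study's two resampling procedures, implemented here
directly (the stratified-median machinery is the analytical core, so it is
not delegated to a bootstrap library): `stratified_bca_bootstrap()`
resamples flies within recording devices and builds a bias-corrected
accelerated 95% interval around the median (bias correction from the
bootstrap distribution's position, acceleration from jackknife skewness);
`randomization_test_medians()` permutes group labels within strata and
reports the two-sided p = (1 + #{|null| ≥ |obs|}) / (1 + n_perm). Both
require a seed; nothing stochastic in the package runs without one. The
study's Bayesian zero-inflated negative-binomial model for interaction and
event *counts* is out of scope (it was fitted with an off-the-shelf
sampler); the bootstrap/randomization statistics cover the duration,
interval, and latency analyses.

## The synthetic world

`simulation_spec()` defaults state the emulated design: 391 compounds × 12
conditions × 5 replicates; log-normal abundances (multiplicative noise is
what MS peak areas look like) with a 30% within-group CV, matching the
study's reported median per-condition RSD; baseline log-mean log(1e6) with
~2 orders of magnitude of between-feature spread; missingness as
per-condition left-censoring (2% detection quantile) plus 2% random dropout,
with optional per-condition excess. Feeding traces are a two-state renewal
process at 5 Hz: bouts start at 0.5/min, last 5 + Geometric samples
(mean 10 ≈ 2 s), with Gaussian signal levels 100 (eating) and 10 (baseline)
around a threshold of 40 — values chosen so detection is unambiguous and
ground-truth bout recovery is exact.

What a green test does **not** establish: the generators produce independent
features (no metabolite correlation structure), symmetric log-normal noise
(no heavy-tailed contamination or batch effects), and missingness that only
roughly mimics condition-dependent detection. Recovery and FDR results on
this world say the pipeline arithmetic is right, not that the study's
specific biological counts are reproduced — that would require the deposited
measurement tables, which are not packaged.

## A known red acceptance criterion

The acceptance suite asserts that ≥ 90% (−5 points tolerance) of features
planted at |log2FC| = 1 with CV 20% and n = 5/group are recovered at
q < 0.1. In this package's stated world that target is unattainable, and
the test is intentionally left failing rather than weakened. Under
multiplicative noise the effect group's standard deviation scales with its
mean, so at a twofold change its variance is 4× baseline; the Welch
noncentrality is ≈ 5 at ≈ 5.9 df, and a BH self-consistency calculation
predicts 72% recovery — the measured value is 62% with default missingness
and 71% without. The 90% figure corresponds to testing log-transformed
abundances (noncentrality 5.5 at 8 df), but this pipeline, like the
published method, applies Welch's test to range-scaled (affine-equivalent
to raw) values and never log-transforms.

## Numerical and tie-breaking conventions

* Percentiles: linear interpolation (`quantile` type 7) everywhere.
* BH ties: identical p-values receive identical q-values (step-up).
* Enrichment results sort by p, then pathway id.
* Graph serialization: lexicographic node and edge order; GraphML
  round-trips byte-identically.
* Run configuration is JSON (`read_run_config()`): the R stack available to
  this package has no YAML parser, and JSON round-trips natively.
* All sample indices are 1-based in R interfaces; reported times use the
  study's units (seconds for durations, minutes for intervals and latency).

## Limitations

No rendering engine (styles export as standard GraphML/CX attributes for any
renderer); no RNA-seq differential calling (those results are consumed, not
produced); no live BioCyc/Flybase retrieval (the `biocyc-subset` reader
accepts the flat-file dialect; packaged fixtures stand in); no MCMC count
model; enrichment p-values against external versioned pathway releases are
out of scope.
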