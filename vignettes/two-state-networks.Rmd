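---
title: "Two-state co-expression networks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state co-expression networks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltnet)
```

## The analysis in one paragraph

`saltnet` asks a simple comparative question of a two-condition
expression experiment: which genes are co-expression hubs *only when the
organism is stressed*?  A gene whose correlation neighborhood is dense
under salt (or other) stress but sparse under control conditions is a
plausible participant in the stress response, and when that gene also
carries sequence variants between a tolerant and a susceptible genotype
and sits inside a trait-associated QTL interval, it becomes a strong
candidate for downstream validation.  The package fits this whole chain
— normalization, per-condition network construction, node centralities,
differential selection, set integration, variant and positional
filtering — as one `saltnet()` call returning a classed object.

## The model and its assumptions

**Normalization.** Size factors follow the median-of-ratios definition:
for sample *j*, `s_j` is the median over reference genes of
`count_ij / geomean_i`, where the reference is every gene with strictly
positive counts in all samples.  This assumes most genes are not
differentially expressed between samples, so the median ratio isolates
compositional depth.  The correlation input is `log2(count/s_j + 1)`;
the log stabilizes the strong mean–variance coupling of counts so that
Pearson correlation reflects co-regulation rather than shared magnitude.
Which transformation feeds the correlation is genuinely open (raw,
normalized, or log counts all appear in practice); the package fixes
log2 with pseudocount 1 as the recorded default because Pearson *r* on
raw counts is dominated by the heavy right tail, and records the choice
in the run summary.

**Networks.** Pearson *r* is computed per condition over that
condition's samples only (at least three required).  The edge rule is
`r >= threshold` with an inclusive comparison and a default threshold of
0.9.  The signed rule is the default; an `absolute` mode (`|r| >=
threshold`) exists because the weighted analysis is explicitly built on
|r|, and negative co-regulation can be of interest.  Edge weights are
always |r|.  By default only supra-threshold edges keep their weight, so
the binary and weighted graphs share one topology and the weighted
surfaces refine, rather than replace, the binary ones; `dense_weights =
TRUE` keeps all |r| for users who want a fully dense weighted graph.
Zero-variance genes cannot be correlated; their correlations are set to
0 (not NA) with a warning so downstream matrices stay total.

**Centralities.** Degree and the Watts–Strogatz clustering coefficient
describe the binary graph; weighted degree and the geometric-mean
weighted clustering coefficient describe the weighted graph.  Both
coefficients are implemented as the ordered double sum over neighbor
pairs divided by `k_i (k_i - 1)`; each unordered pair is counted twice
in numerator and denominator, which equals the more familiar
"triangles over possible pairs" form (a property test asserts the
equivalence).  In the weighted form, `k_i` counts neighbors with nonzero
weight, and edge weights must lie in [0, 1] — guaranteed upstream since
weights are absolute correlations — so both coefficients are guaranteed
to lie in [0, 1].  Nodes of degree < 2 have an undefined denominator;
they are assigned 0, the common graph-library convention, so metric
tables have no missing values.

**Differential selection.** "High under stress, low under normal" needs
numbers to be reproducible.  Three rules are provided; the default is
the percentile rule: stress metric at or above the 90th percentile of
the stress-state distribution and normal metric at or below the median
of the normal-state distribution (empirical quantiles, R's default
type 7).  Absolute thresholds and a top-k rule on the stress−normal gap
are alternatives.  All tie-breaking is lexicographic on gene id, so
results do not depend on platform ordering.  The WGCN method ranks on
weighted degree by default (weighted clustering is computed and reported
alongside; `wgcn_rank = "wcc"` switches the ranking key).

**Integration.** The three candidate sets are partitioned into the
seven disjoint Venn regions.  The SNP filter keeps genes with at least
one variant record, optionally restricted to chosen region classes
(promoter, UTRs, exons, introns); presence, not count, is the criterion.
The interval filter uses BED semantics — 0-based half-open coordinates
and any-overlap (`gene.start < q.end && q.start < gene.end`), with full
containment available by flag — because "located in" a QTL without a
stated boundary rule is best served by the standard convention.  Both
filters are pure membership filters, hence contractive and commuting,
which a property test asserts.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `edge_threshold` | 0.9 | correlation cutoff (inclusive), unitless *r* |
| `edge_mode` | signed | `signed` uses *r*, `absolute` uses \|*r*\| |
| `pseudocount` | 1 | offset inside `log2(count/s + .)` |
| `stress_min_percentile` | 90 | stress-side cut of the percentile rule |
| `normal_max_percentile` | 50 | normal-side cut of the percentile rule |
| `snp_region_classes` | all | which variant classes count as evidence |
| `interval_mode` | overlap | QTL filter: any overlap vs containment |

The 90/50 percentile pair is deliberately asymmetric: the stress cut
must isolate the hub tail, while the normal cut only needs to exclude
genes that are hubs in both states (constitutive modules), for which
the median is sufficient in panels where most genes are sparsely
connected.

## What the synthetic generator emulates

`sim_config()` describes a panel of `n_genes` genes of which
`n_modules × module_size` belong to co-expression modules; the first
`n_planted` genes are "planted" differential hubs.  Each module has a
per-sample latent factor; a member gene's log-expression is
`sqrt(rho) * factor + sqrt(1 - rho) * noise` with `rho = rho_on` when
the module is active and `rho = rho_off` for planted genes under the
normal condition.  Counts are drawn negative-binomially around
`exp(mean_log_expression + sd_log_expression * signal)` with dispersion
`nb_dispersion`.

Two construction details matter:

* **Correlations are planted in the empirical sense.**  The module
  factor is standardized to unit sample variance and each gene's noise
  vector is residualized against it before mixing.  With a plain iid
  draw, the realized within-module correlation at n = 30 samples
  carries Fisher sampling noise of ±0.02–0.03 around `rho`, so whole
  modules drift below a 0.9 edge threshold at random and edge formation
  cannot be predicted from `rho` — defeating the generator's purpose as
  a ground-truth instrument.  After standardization the realized
  correlation concentrates at `rho` with jitter of order
  `(1 - rho)/sqrt(n)`, and the edge rule behaves deterministically at
  the design point.
* **Noise calibration.**  Count-layer noise attenuates correlations by
  roughly `1/(1 + v)` with `v = (1/mu + dispersion)/sd_log^2`, and
  median-of-ratios factors remove a further ~1.5 % because the median
  partially tracks the module factors.  The defaults — dispersion
  0.005, mean log-expression 7 (≈1100 counts), log-signal SD 1.5 —
  keep the realized within-module correlation at 0.944 for
  `rho_on = 0.95`, i.e. the planted correlation is approximately
  recovered after normalization and transform, as the design requires.
  These values describe a well-expressed, differentially expressed gene
  panel: large biological spread (the latent factor), modest residual
  overdispersion around it.

The default configuration (600 genes, 10 modules × 20, 30 planted, 30
samples per state, `rho_on = 0.95`, `rho_off = 0`) runs the full
pipeline in about a second and is the problem size used throughout the
tests and the acceptance script; recovery there is essentially perfect
(union recall and precision ≈ 1 across seed batches, computed by
`planted_recovery()`).

What the generator does **not** emulate: multi-tissue/stage block
structure within a state (real two-state panels pool several tissues,
adding between-tissue correlation the generator lacks), library-size
variation beyond what median-of-ratios trivially absorbs, isoform
structure, time-course autocorrelation, and hub genes embedded in
overlapping modules.  Passing tests therefore demonstrate that the
machinery recovers clean planted signal under its own assumptions — not
that the 90/50 percentile rule is well calibrated for any particular
real data set, where module sizes, correlation strengths and the DEG
pre-filter all differ.

## Numerical conventions and degenerate inputs

* Quantiles: R default (type 7).  With heavily tied degree
  distributions the stress cut typically lands exactly on the modal hub
  degree; the inclusive `>=` then admits the whole tied group.
* Zero-variance genes: *r* = 0 against all partners, diagonal 0,
  flagged by a warning.
* Degree < 2: both clustering coefficients are 0.
* Empty inputs: an empty gene panel produces empty networks, an empty
  metrics table produces empty candidate sets, and an empty SNP table
  empties the final list — every stage stays total.
* Gene panels, candidate sets and output tables are sorted
  lexicographically; reruns of one configuration are byte-identical.
* SNP records with `ref == alt` are dropped (counted, warned);
  unrecognized region classes map to `unknown`.
* Coordinates: annotation and intervals are BED (0-based half-open);
  SNP positions are VCF-style 1-based.

## Known limitations

* Pearson-only correlation; rank-based or biweight alternatives are out
  of scope, as is soft-threshold (power) adjacency.
* No statistical calibration of the differential rule (no permutation
  p-values); the selection is a deterministic screen, by design.
* The SNP filter treats the variant table as given evidence; calling
  and filtering variants is upstream of this package.
* Differential-expression pre-filtering is accepted as a gene list, not
  recomputed; pairing the package with a count-based DE tool for that
  step is recommended.

## Pigment utility

`pigment_contents()` evaluates the standard spectrophotometric
equations (chlorophyll *a* = 12.25·A663.2 − 2.79·A646.8, chlorophyll
*b* = 21.5·A646.8 − 5.1·A663.2, carotenoids = (100·A470 − 1.82·Chl a −
85.02·Chl b)/198).  Negative outputs are returned as-is with a warning
rather than clamped: a negative pigment content is a data problem the
user should see, not one the software should hide.
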