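---
title: "Molecular and spatial heterogeneity metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular and spatial heterogeneity metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cellhet` quantifies two complementary aspects of tumor heterogeneity from
spatially resolved per-cell marker tables: how diverse the molecular
states of a sample's cells are, and how that diversity is organized in
space. This vignette explains the underlying model, every tunable
parameter that matters, the synthetic data the package validates itself
on, and the design decisions taken where the methodology left genuine
choices open.

## The state model

A *hallmark set* is a small ordered list of markers assigned to one
cancer hallmark — for example proliferative signaling (EGFR, Ki67,
Nestin) or angiogenesis (SMA, VEGFR2, CD31, S100A4). Each marker's
per-cell intensity is quantized into an ordinal level — low (0), medium
(1) or high (2) — at the marker's 33rd and 67th empirical quantiles.
Concatenating a cell's levels in the set's fixed marker order yields its
*molecular state*, read as a base-3 code with the first marker least
significant. An `m`-marker set therefore has `Nm = 3^m` possible states:
27 for three markers, 81 for four. The marker order is arbitrary but must
be held fixed; permuting it permutes the codes without changing the
state *distribution*, so both entropy metrics are order-invariant (this
is tested).

Two conventions are fixed and tested rather than left implicit:

* **Quantile rule.** Empirical quantiles use linear interpolation between
  order statistics (`stats::quantile()` type 7). Any consistent rule
  would do; this one is the R default and is pinned by an independent
  sorted-order oracle in the tests.
* **Boundary convention.** `value <= q33` is low, `q33 < value <= q67` is
  medium, `value > q67` is high. Ties at the thresholds are common in
  real intensity data, so the half-open-upper convention matters and is
  asserted at the boundaries.

**Threshold scope.** By default the quantiles are fitted on all
quality-passing cells of the cohort pooled across groups, because
comparing heterogeneity between samples only makes sense under a common
state definition. A per-sample scope is available
(`fit_quantization(..., scope = "sample")`) for exploratory use; every
quantization model records its scope and can be serialized to YAML so the
exact state definition is reusable across runs.

**Degenerate markers.** A constant marker yields `q33 == q67`; all cells
then receive level 0 and the marker is flagged. This is deterministic and
introduces no spurious diversity.

## The two metrics

*Molecular heterogeneity* is the normalized Shannon entropy of the
molecular-state frequencies `Pm_i` within one sample,
`-sum_i Pm_i ln(Pm_i) / ln(Nm)`, with `0 ln 0 := 0`. It is 0 exactly when
all cells occupy one state and 1 exactly when cells are uniform over all
`Nm` states. Natural logarithms are used throughout; the normalization
makes the base irrelevant.

*Spatial heterogeneity* relies on the cell-contact graph: two cells of
one sample are neighbors when their centroid distance is strictly less
than `contact_factor = 1.3` times the sum of their circle-equivalent
radii (`r = sqrt(area/pi)`). A cell's *spatial state* is the number of
its neighbors sharing its exact molecular state — exact state-code
equality over all markers of the set, not per-marker partial matching —
and zero is a valid state. The metric is the normalized entropy of the
spatial-state frequencies, `-sum_k Ps_k ln(Ps_k) / ln(Zmax + 1)` over
`k = 0..Zmax`, where `Zmax` is the maximum neighbor count observed in
that sample.

Two consequences of this definition deserve emphasis:

* `Zmax` is a *per-sample* quantity. Metrics are therefore comparable
  across samples only as normalized values, which is how they are used.
* If every cell is isolated (`Zmax = 0`) the normalizer `ln(1)` vanishes;
  only one spatial state is then possible, so the metric is defined as 0.
  This convention is tested.

The neighbor search uses a uniform-grid spatial index whose bucket width
bounds the largest possible contact distance (`2 * 1.3 * max(r)`), so the
edge set is provably identical to the all-pairs computation; the tests
assert edge-for-edge equality against an O(n²) brute-force oracle.

## Quality filtering and transforms

Cells enter the analysis only if their registration quality score is
*strictly greater* than 0.85 (the conventional cutoff for
registration-based quality scores in iterative-staining data; the
threshold is a parameter). Intensities used for clustering are
log2-transformed; a pseudocount is required when zeros are present
(default 1 in that case, 0 otherwise).

## Phenotype clustering workflow

Clustering operates on log2 intensities that are *trimmed* at the 2.5th
and 97.5th per-marker percentiles and then z-standardized by the
post-trim mean and SD. Trimming is implemented as winsorization
(clipping) rather than cell removal, so the cell set stays intact for the
downstream spatial and composition analyses; a cell-removal variant is
available (`method = "exclude"`). Whether the original procedure trimmed
values or removed cells, and whether standardization statistics preceded
the trim, are genuinely open readings; winsorize-then-standardize is the
default here and both choices are explicit in the API.

K-means (squared-Euclidean, `stats::kmeans`, best of `n_starts = 10`
random starts, K = 2–15 by default) is scanned across K with three
selection metrics recorded per K — mean silhouette width, the
Calinski–Harabasz criterion, and the within-cluster SSE — plus consensus
clustering: repeated K-means on random 80% subsamples (without
replacement) of up to 5,000 cells, 1,000 iterations by default, with the
consensus of a cell pair defined as its co-clustering count divided by
its co-sampling count. Pairs never co-sampled are reported as missing,
not zero. The per-K consensus CDF, its area, and the proportion of
ambiguous pairs (PAC, consensus in (0.1, 0.9)) summarize sharpness.

`choose_k()` never silently auto-selects: it emits the full per-K report
and a recommendation by an explicit rule — the smallest K at which the
relative gain in consensus CDF area drops below 0.1, tie-broken by
silhouette; without consensus results, the silhouette maximum. The
recommendation is flagged *unreliable* when no criterion shows a distinct
optimum (maximum silhouette below 0.25, or a silhouette profile flat to
within 0.1), and a *disagreement* flag is raised when silhouette and the
consensus rule differ.

Cluster profiles (lollipop values) are per-cluster, per-marker mean
deviations from the population mean in the standardized analysis space;
size-weighted deviations sum to zero per marker by construction. Sample
compositions are per-sample cluster fractions summing to one.

## Group comparison and integration

Group tests operate on *per-subject* summaries, never on per-cell values:
the unpaired Student's t-test with pooled variance (Welch by flag) for
mean-level contrasts, and the Mann–Whitney rank-sum test for
heterogeneity metrics — exact p-values for small samples without ties,
normal approximation otherwise (the `stats::wilcox.test` policy). In line
with the conventions of cell-level imaging studies, p-values are not
adjusted for multiple testing by default; `p.adjust` can be applied
downstream where appropriate. Pearson correlation is provided for
slide-to-slide replicate checks.

For multimodal integration, per-subject features are discretized into
low/medium/high. "Based on the data ranges" admits two readings, so both
are implemented and labelled: equal-width range thirds (default;
half-open upper boundaries, maximum assigned to high) and tertiles at the
33rd/67th quantiles. Constant features are flagged and assigned medium.
Subjects are then clustered by agglomerative hierarchical clustering on
Euclidean distances of the ordinal (0/1/2) vectors. Only the distance
metric is prescribed by the methodology; the linkage is a free choice,
average linkage is the default, and the linkage used is recorded in every
result.

## The synthetic cohort generator

The generator produces the reference study conditions every test and the
acceptance script run under. Each subject contributes one rectangular
field (600 × 600 length units by default) of 1,000 cells with uniform
centroids, truncated-normal radii (mean 5, SD 1, r > 0, areas `pi r²`),
and uniform quality scores on [0.7, 1] — so roughly half the cells pass
the 0.85 filter, exercising it nontrivially.

Every cell carries a latent phenotype. Spatial organization comes from
*seeded nearest-phenotype assignment*: 25 seed points per field each
carry a phenotype, and a cell adopts its nearest seed's phenotype with
probability `1 - scatter_prob`, otherwise a uniformly random phenotype of
its group. `scatter_prob` therefore dials spatial aggregation from
patch-like (0) to fully mixed (1). A Gaussian random field could produce
smoother textures, but seeded assignment is exactly controllable and is
sufficient to modulate the spatial metric, which is what the tests need.

Marker intensities are log-normal: normal on the log2 scale around the
phenotype's per-marker mean with SD 0.5, matching the log2 analysis
scale. Phenotype mean profiles are explicit ordinal anchors: phenotype 1
is pan-low, phenotype 2 pan-high, phenotype 3 pan-medium, and each
further phenotype deviates from pan-medium on two cycling markers (one
up, one down), with 2 log2 units (4 within-phenotype SD) between adjacent
levels. This design was chosen deliberately: under cohort-pooled tertile
thresholds, what matters is where the thresholds fall relative to the
expression modes. Anchor profiles keep each marker's pooled level masses
near one third, so thresholds land between modes and quantized levels
track phenotypes; mean schemes that concentrate pooled mass unevenly let
a threshold fall *inside* a mode, splitting same-phenotype cells by noise
and inflating the entropy of the very group that should be homogeneous.

The default two-group design is "mt-like" (2 phenotypes,
`scatter_prob = 0.05`: few, spatially aggregated populations) versus
"wt-like" (6 phenotypes, `scatter_prob = 0.95`: many, spatially mixed),
10 subjects per group. This plants the qualitative contrast the metrics
are meant to detect — lower molecular heterogeneity and higher spatial
heterogeneity in the mt-like group — and the ground-truth phenotype is
stored in a `phenotype` column that no analysis function reads; it exists
only for validation.

What the generator does *not* emulate: staining-round artifacts,
autofluorescence, segmentation errors, cell-shape anisotropy, marker–
marker correlations beyond the phenotype structure, or tissue
architecture (vessels, necrosis). Passing tests therefore demonstrate
correctness of the computations and sensitivity under idealized
conditions, not performance on real tissue.

## Problem sizes and numerical choices

The validation suite uses deliberately modest problem sizes chosen as the
package's own reference conditions: cohorts of 10 + 10 subjects at 1,000
cells each for parameter recovery; 5,000 cells for the 7-phenotype
clustering recovery, with consensus on a 1,000-cell subsample at 40
iterations and 3 starts per iteration (the full 5,000 / 1,000 / 80%
defaults remain available); and 1,000 simulated null cohorts of 8 + 8
subjects at 120 cells for the rank test's type-I calibration — at 8 vs 8
the exact Mann–Whitney achievable level nearest 0.05 is 0.0499, so the
calibration target is meaningful. All randomness flows from explicit
seeds; K-means determinism is guaranteed by seeding, and the rare
empty-cluster failure of Hartigan–Wong K-means is handled by retrying
with fresh starts.

Known limitations: the spatial metric depends on cell density through
`Zmax`, so sparse samples compress its dynamic range; consensus
clustering at full defaults is the slowest stage (minutes, by design of
the procedure); and with duplicate tissue cores per subject the package
computes per-core metrics and offers mean pooling (`pool_subject_metrics`)
— whether pooling or per-core analysis is preferable is a study-design
question the package leaves to the analyst, reporting both.
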