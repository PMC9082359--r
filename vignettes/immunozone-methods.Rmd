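---
title: "Methods: spatial immune quantification and molecular subgrouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune quantification and molecular subgrouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunozone)
```

## Overview

`immunozone` quantifies the spatial arrangement of immune cells around
tumor-cell nests in multiplex IHC of tissue-microarray (TMA) cores and
compares molecular subgroups of pancreatic ductal adenocarcinoma (PDAC).
The pipeline starts from *labeled cells* — one row per detected cell with
planar coordinates in micrometers and a class (tumor, CD8⁺ T-cell, FOXP3⁺
regulatory T-cell, CD68⁺ macrophage, other) — as produced by any image
analysis platform. Image processing, stain deconvolution and cell
segmentation are explicitly out of scope.

## Tumor-cluster geometry

Tumor nests are modeled as the union of discs of radius `merge_radius`
centred on tumor cells. Connected components of the union are the
clusters; components supported by fewer than `min_cells` tumor cells are
dropped as isolated cells or debris.

* `merge_radius` = 15 µm by default: roughly one epithelial cell diameter
  of slack, which fuses gland-like nests without bridging across stroma.
* `min_cells` = 5 by default.

Discs are approximated by regular 64-gons (area error < 0.2%, fully
deterministic) and the union is computed with exact polygon boolean
operations (Clipper, via the `polyclip` package). Distances are signed
Euclidean distances to the union boundary, negative inside a nest,
evaluated by a compiled point-to-segment kernel with even–odd
point-in-polygon sign tests. Because the boundary is a 64-gon
approximation and disc polygons have a fixed vertex orientation, areas and
distances are rotation-invariant only to about 10⁻⁴ relative — the test
suite asserts invariance at that level, not at machine precision.

Exclusion regions (necrosis, vessels, acinar and islet tissue) are
subtracted from the *area denominator* but the pre-exclusion outline is
kept for distance banding: a necrotic hole inside a tumor nest should not
relabel the cells around it as stromal. This behavior follows the
documented analysis convention; the alternative (excluding the outline
too) would be a one-line change in `build_tumor_clusters()`.

Degenerate inputs: a core without tumor cells (or whose components all
fail `min_cells`) yields an empty cluster set with zero area; such cores
are dropped from density computation with a logged warning, because the
denominator is undefined. Cells exactly on a boundary count as inside
(signed distance 0, hence intra-tumoral).

## Compartments

Each non-tumor cell is banded by its signed distance *d* to the cluster
perimeter:

| compartment | rule | default |
|---|---|---|
| intra-tumoral | *d* ≤ `intra_max` (includes *d* < 0) | 10 µm |
| peri-tumoral | `intra_max` < *d* ≤ `peri_max` | 50 µm |
| stromal | *d* > `peri_max` | — |

Band boundaries are closed on the inner side ("within 10 µm" read as
inclusive). The choice affects a measure-zero set of cells and cannot
change densities, but it is fixed for determinism. Distance is measured
from the cell *centroid* to the cluster *perimeter*, and the same
perimeter is used for both the intra- and peri-tumoral bands; measuring
the inner band from individual tumor-cell edges instead would require
per-cell morphology that coordinate tables do not carry.

## Per-case metrics

* **Densities**: per core, count / total tumor-cluster area (mm²); per
  case, the arithmetic mean over evaluable replicate cores. Following the stated
  normalization convention, *all three* compartments use
  the tumor-cluster area as denominator. This makes stromal "densities"
  large relative to true stromal intensities (the stromal region is much
  larger than the nest area); they are comparable across cases, which is
  all the group tests require. Per-compartment areas for true intensities
  are available via `compartment_areas()` when a core boundary is known.
* **CD8⁺:FOXP3⁺ ratio**: per core, whole-core CD8 total / FOXP3 total
  (all compartments combined); cores with zero FOXP3⁺ cells are excluded
  from the case mean rather than given infinity or a pseudocount — this
  keeps the case value finite without inventing a floor.
* **CPS**: per core, 100 × (PD-L1⁺ tumor cells + lymphocytes +
  macrophages) / viable tumor cells, capped at 100 per the clinical
  convention; cores without viable tumor cells are unevaluable. The case
  CPS is the mean over evaluable cores and is *positive* when ≥ 1.
* **log-floor transform**: for display on log scale, zero counts are
  replaced by 90% of the smallest non-zero value among the cases
  evaluated, then log₁₀ is applied. Group comparisons use the *raw*
  densities — the transform is monotone, so the rank-based Wilcoxon test
  is unaffected either way; raw values keep reported means in cells/mm².

## Molecular subgrouping

Decision order in `classify_case()`:

1. **MMR-d** — IHC loss of any assessed MMR protein (MLH1, MSH2, MSH6,
   PMS2) or MSIsensor ≥ 20. A germline MMR-gene mutation alone does not
   qualify. MMR-d is checked first because it is the established
   ICI-responsive reference class; no case in the bundled data exercises
   the precedence, so this is a documented convention rather than an
   empirical constraint.
2. **HR-d, germline path** — germline *BRCA1*/*BRCA2*/*PALB2* carrier:
   HR-d if no HRDetect score is available, if HRDetect ≥ 0.9 (inclusive),
   or if the case carries an explicit low-tumor-cellularity flag and
   HRDetect > 0.7 (exclusive). A carrier below threshold is considered
   HR-intact. The low-cellularity exception is an explicit per-case
   override flag, not an automatic cellularity computation, because it
   was applied ad hoc to a single documented case.
3. **HR-d, somatic path** — no germline hit: HRDetect > 0.9 (exclusive,
   exactly as printed) *and* somatic HR-gene inactivation.
4. Everything else — including cases with no evaluable molecular data —
   is **HR/MMR-intact**.

HRDetect and MSIsensor are consumed as precomputed inputs; computing them
is out of scope. The bundled `inst/extdata/pdac_hrd_annotations.tsv`
transcribes the 26 molecularly characterized (HR-d/MMR-d) cases of a
published 192-case PDAC cohort and classifies into 25 HR-d and 1 MMR-d,
exercising the germline, somatic-only, low-cellularity and IHC-loss paths.

## Cohort statistics

* Wilcoxon rank-sum, two-sided; exact enumeration when the combined n is
  ≤ 20 with no ties, otherwise the normal approximation with tie and
  continuity corrections.
* Fisher's exact test, two-sided (summing hypergeometric probabilities of
  tables as or less probable than the observed one); degenerate margins
  return p = 1 with a warning instead of failing the pipeline.
* Kaplan–Meier product-limit curves; the median is the *earliest time at
  which the curve reaches ≤ 0.5* (undefined while the curve stays above
  0.5) — note this differs from `survival::survfit`'s midpoint convention
  when the curve hits 0.5 exactly. Two-group log-rank χ² with 1 df.
* P-values are reported unadjusted, mirroring common practice for this
  kind of descriptive cohort comparison; `p_adjust = "BH"` applies
  Benjamini–Hochberg across the density and score comparisons for
  reuse on larger metric panels.

## The synthetic-cohort generator

`simulate_core()` builds one TMA core:

* a 1.5-mm circular core (default) containing `n_clusters` = 4 tumor
  nests; each nest scatters 350 tumor cells from a truncated Gaussian
  (SD = radius/2, truncated at the radius) around a uniformly placed
  centre, with a per-nest radius ~ N(180, 30) µm. These defaults give a
  total cluster area of ≈ 0.3 mm² in a 1.77 mm² core — a realistic tumor
  fraction for a stroma-rich carcinoma — and were fixed once.
* the *true* nest geometry is the same disc union the analysis
  reconstructs (same `merge_radius`/`min_cells`), so compartment
  assignment is exact by construction and parameter recovery isolates
  the Poisson sampling error.
* immune cells are a homogeneous Poisson process per (phenotype,
  compartment): counts ~ Poisson(intensity × compartment area), positions
  by rejection sampling of uniform points in the core against the true
  compartment geometry (dilations of the nests by 10 and 50 µm, clipped
  to the core). Intra-tumoral default intensities are the published group
  means (CD8⁺ 40.5 vs 131.1 cells/mm², FOXP3⁺ 13.6 vs 25.5 cells/mm² for
  intact vs HR-d); peri-tumoral/stromal intensities and the CD68⁺ profile
  are not printed anywhere and were chosen once as plausible values,
  identical between groups (matching the reported absence of
  peri-tumoral/stromal differences).
* PD-L1 positivity is a per-class Bernoulli draw (tumor cell, lymphocyte,
  macrophage).

`simulate_cohort()` adds the case level:

* default group sizes 166 / 25 / 1 (intact / HR-d / MMR-d), 3 cores per
  case sharing case-level parameters;
* a per-case, per-phenotype lognormal intensity multiplier
  (sdlog = 0.8). The published group summaries have SD ≈ mean, far more
  dispersed than Poisson; only the group *means/SDs* are printed, so the
  lognormal shape is an assumption, flagged as such;
* a per-case lognormal PD-L1 propensity multiplier (sdlog = 1.5),
  producing the observed pattern of a few strongly positive cases over a
  near-zero background;
* molecular annotations constructed to be rule-consistent with the
  intended subgroup (all decision paths represented; verified by a 100%
  recovery property test);
* survival ~ Exponential(log 2 / median) with defaults 19.9 (intact) and
  29.1 (HR-d) months and administrative censoring at 60 months — real
  censoring mechanisms are rarely reported, so the simplest one was
  chosen;
* stage (early/late) ~ Bernoulli with the published group proportions
  (7/166, 13/25);
* reproducibility: one root seed; each (case, core) gets a substream seed
  by deterministic Lehmer-style mixing of (seed, case index, core index),
  so outputs do not depend on generation order.

What the generator does **not** emulate: segmentation or classification
error, staining artifacts, spatial clustering of immune cells beyond the
compartment structure (no attraction/repulsion within a compartment),
within-case core heterogeneity beyond Poisson noise, or informative
censoring. Passing calibration tests therefore demonstrates correctness
of the *pipeline* under its own assumptions, not robustness to
upstream imaging errors.

## Calibration results asserted by the test suite

The simulation-based checks in `tests/testthat/test-acceptance.R` assert,
at the problem sizes chosen to keep the suite fast:

* compartment partition and agreement with a brute-force
  boundary-sampling oracle on 1,000 randomized small cores (500–800 µm,
  1–2 nests of 40–80 cells); cells within 0.3 µm of a band boundary are
  compared leniently because the sampled oracle itself carries up to
  0.125 µm of discretization error, and are verified to be < 2% of cells;
* 95% Poisson intervals for per-compartment intensity estimates cover the
  generator truth in ≥ 90% of 500 × 9 cases;
* Wilcoxon type-I error ≈ 5% over 200 null cohort replicates (8 vs 8
  cases, single small cores), and power ≥ 95% over 20 replicates for the
  intra-tumoral CD8⁺ comparison at the published intensities and group
  sizes (25 vs 166 cases; single small cores per case, which only *adds*
  Poisson noise relative to the full-size design), with equal-intensity
  compartments not enriched for rejections;
* the Fisher implementation matches exhaustive hypergeometric enumeration
  for every 2×2 table with n ≤ 40, and the exact Wilcoxon branch matches
  full permutation enumeration for combined n ≤ 12.

One documented simulator property was *not* adopted as a test: the
Kaplan–Meier median of an exponential sample of 25 (median 29.1 months,
censored at 60) falls within ±25% of the truth in only ~62% of
replicates, so per-replicate median recovery is asserted for the n = 166
group only, with unbiasedness across replicates for the n = 25 group.

## Known limitations

* Distances are centroid-to-perimeter; platforms measuring from cell
  edges will shift the intra-tumoral band by roughly a cell radius.
* Stromal areas are unbounded without a core boundary, so true stromal
  intensities require the core outline (`compartment_areas()`); the
  default cluster-area normalization sidesteps this at the cost of
  interpretability of the stromal column.
* The CD8⁺:FOXP3⁺ exclusion rule discards FOXP3-free cores, which biases
  the case mean upward in sparsely infiltrated cases; with 2–3 replicate
  cores no unbiased alternative exists without a pseudocount.
* The classifier encodes printed thresholds verbatim (≥ 0.9 vs > 0.9 vs
  > 0.7); these are established clinical conventions, not re-derived
  quantities.
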