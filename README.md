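# immunozone

Compartmentalized spatial quantification of the tumor–immune
microenvironment, with rule-based molecular subgrouping, for multiplex
immunohistochemistry (IHC) of tissue-microarray cores.

## The scientific problem

Pancreatic ductal adenocarcinoma (PDAC) is usually an immunologically
"cold" tumor, but molecular subtypes differ: mismatch-repair-deficient
(MMR-d) PDAC responds to immune-checkpoint inhibition, and the more common
homologous-recombination-deficient (HR-d) subtype (germline or somatic
*BRCA1*/*BRCA2*/*PALB2* inactivation) is suspected to be immunogenic as
well. Testing that hypothesis from stained tissue requires quantifying
*where* immune cells sit relative to tumor cell nests, not just how many
there are.

`immunozone` implements that pipeline from per-cell coordinate tables (the
output of any cell-classification platform):

1. **Tumor-cluster geometry** — tumor nests are reconstructed as connected
   components of the union of discs of radius *r* (default 15 µm) around
   tumor cells; components with fewer than 5 tumor cells are discarded.
   Necrosis/vessel/acinar/islet exclusion regions are subtracted from the
   area denominator while the pre-exclusion outline is kept for distances.
2. **Compartments** — each immune cell is banded by its signed Euclidean
   distance *d* to the nest perimeter: **intra-tumoral** (*d* ≤ 10 µm,
   including cells inside a nest), **peri-tumoral** (10 < *d* ≤ 50 µm),
   **stromal** (*d* > 50 µm).
3. **Per-case metrics** — densities = counts / total tumor-cluster area
   (mm²), averaged over replicate cores; CD8⁺:FOXP3⁺ ratio (whole-core
   totals, FOXP3-free cores excluded); PD-L1 Combined Positive Score,
   CPS = 100 × (PD-L1⁺ tumor cells + lymphocytes + macrophages) / viable
   tumor cells, capped at 100, case-positive when the core-averaged CPS
   ≥ 1. A log₁₀ transform with a 0.9 × min(non-zero) floor for zeros is
   provided for display.
4. **Molecular subgroups** — HR-d: germline *BRCA1*/*BRCA2*/*PALB2* plus
   (when sequenced) HRDetect ≥ 0.9, with a documented > 0.7
   low-tumor-cellularity exception, or — without a germline hit —
   HRDetect > 0.9 together with somatic HR-gene inactivation. MMR-d
   (checked first): IHC loss of any of MLH1/MSH2/MSH6/PMS2 or MSIsensor
   ≥ 20. Everything else, including unevaluable cases, is HR/MMR-intact.
5. **Cohort statistics** — Wilcoxon rank-sum per (phenotype, compartment),
   Fisher's exact test on CPS-positivity proportions, Kaplan–Meier medians
   with a log-rank test.

A spatial point-process simulator (`simulate_core()`, `simulate_cohort()`)
generates synthetic cores with known compartment intensities, rule-consistent
molecular annotations and exponential survival, and is used throughout the
test suite for calibration (type-I error, power, parameter recovery).

## Worked example

```r
library(immunozone)

cfg <- cohort_sim_config(
  n_cases_per_group = c(HR_d = 10, HR_MMR_intact = 20),
  cores_per_case = 2,
  core = core_sim_config(core_diameter = 900, n_clusters = 2,
                         cluster_radius_mean = 120, cluster_radius_sd = 15,
                         n_tumor_cells_per_cluster = 150),
  seed = 2024)
sim <- simulate_cohort(cfg)
out <- run_pipeline(sim$cells, sim$annotations, clinical = sim$clinical)
out$report
```

```
<cohort_comparison> HR_d vs HR_MMR_intact
Densities (cells/mm^2, mean +/- SD; Wilcoxon p):
# A tibble: 9 × 11
  metric phenotype zone    n_1   n_2 mean_1  sd_1 mean_2  sd_2 p_value evaluable
1 densi… CD8       intr…    10    20  237.  194.    52.1  48.9 3.36e-4 TRUE
2 densi… CD8       peri…    10    20   82.5  72.2   65.0  50.5 5.82e-1 TRUE
3 densi… CD8       stro…    10    20  833.  766.   587.  384.  7.75e-1 TRUE
4 densi… FOXP3     intr…    10    20   58.1  64.8   18.1  13.4 2.47e-2 TRUE
...
Scores:
1 cd8_foxp3_ratio ... p_value 0.809
2 cps             ... p_value 0.0157
PD-L1 positivity (CPS >= 1; Fisher p = 0.103)
<km_result> log-rank p = 0.601
```

The simulated HR-d group was given a higher *intra-tumoral* CD8⁺/FOXP3⁺
intensity only, and the report recovers exactly that signature: strong
intra-tumoral Wilcoxon p-values, null peri-tumoral/stromal comparisons,
and an elevated CPS. `tidy()` and `glance()` return the same report as
tibbles; `autoplot()` draws the grouped density comparison, and
`plot_core_zones()` maps a single core.

Classifying a real annotation table:

```r
ann <- read_annotation_table(system.file("extdata",
        "pdac_hrd_annotations.tsv", package = "immunozone"))
table(classify_table(ann)$subgroup)
#> HR_MMR_intact          HR_d         MMR_d
#>             0            25             1
```

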