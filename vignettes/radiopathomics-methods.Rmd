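---
title: "Cross-scale association of CT radiomics and cell-density pathomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale association of CT radiomics and cell-density pathomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiopathomics)
```

## The problem

In immunotherapy-treated non-small cell lung cancer, two routinely acquired
imaging modalities describe the tumor at very different scales: CT scans
(macro-scale, quantified as *radiomics* feature tables) and digitized H&E
histology slides (micro-scale, quantified here as *pathomics* features of
cell-density maps). This package implements the full analysis chain for
asking whether, and where, the two feature spaces carry shared information:
per-feature Spearman cross-correlation, comparison of the two modalities'
correlation profiles against clinical endpoints (overall survival,
progression-free survival, CD8-positive immune infiltration) with a
two-sample Kolmogorov–Smirnov test, and two-cluster hierarchical patient
stratification per modality.

Because cohorts of this kind are small and the underlying patient data are
typically private, the package ships a seeded synthetic-cohort generator
with known planted structure. Every pipeline stage is validated by parameter
recovery on those cohorts rather than by reproducing any specific cohort's
values.

## Pathomics: from tile to feature table

**Tissue masking.** `compute_tissue_mask()` applies, in order: ITU-R 601
luminance grayscale, Otsu thresholding with tissue taken as the darker
class, binary dilation (disk radius 2), filling of enclosed holes smaller
than 256 px, and removal of connected components smaller than 1024 px. The
hole/object area defaults are working-resolution choices and are
configurable; the literature this pipeline follows does not fix them. A
caveat worth stating plainly: grayscale-plus-Otsu masking presumes
slide-scale imagery in which the dominant contrast is tissue versus bright
glass. On a single high-magnification patch that is entirely tissue, the
histogram's two modes are nuclei versus cytoplasm, so Otsu isolates the
nuclei and the "tissue fraction" of such a patch is near the
nucleus-pixel fraction, not 1. The pipeline therefore applies tissue
masking when given slide imagery, and treats pre-tiled inputs (including
synthetic tiles) as already-extracted patches subject only to the
nucleus-score filter.

**Patching.** `extract_patches()` tiles the image with a non-overlapping
grid from the top-left origin (0-based, half-open coordinates); partial
edge tiles are discarded and a patch is kept when its within-patch mask
mean is at least the tissue threshold (default 0.8). Exhaustive
grid-plus-threshold extraction is used rather than score ranking: every
qualifying patch enters the analysis. Patches are 512 px square by default
and carry magnification as metadata only.

**Nucleus scoring and the 15% rule.** A single nucleus-pixel classifier is
shared by patch scoring and segmentation seeding: a hematoxylin-like
channel `0.5*(255-R) + 0.5*(255-G)` (chromatin absorbs red and green;
eosin-pink cytoplasm does not), a fixed absolute threshold of 100 (0–255
units), and a morphological opening of radius 2 to remove specks. The
threshold is deliberately absolute rather than adaptive so that an
all-background patch scores ~0 instead of producing a degenerate split.
`filter_patches()` retains patches whose nucleus-pixel fraction is at
least 0.15, boundary inclusive.

**Watershed segmentation.** `segment_nuclei()` follows the classic
marker-controlled recipe: classification, opening, hole filling, Euclidean
distance transform, sure-foreground markers where distance exceeds
`fg_frac` (default 0.4) of the maximum, and watershed growth of the
markers across the nucleus mask. The geometry of this scheme is exactly
characterizable on disks: two radius-`r` disks with centers `d` apart have
a distance-transform saddle of height `sqrt(r^2 - (d/2)^2)` and split into
two labels precisely when that saddle falls below `fg_frac * r`. At the
default 0.4 this resolves overlaps shallower than about `0.17 r`; the test
suite pins both sides of that analytic boundary. Per-nucleus area and
eccentricity are recorded, and `categorize_nuclei()` attaches
small/medium/large and round/elongated categories (eccentricity cutoff
0.8) as metadata; the texture features below do not use them.

**Density maps.** `density_map()` divides a patch into non-overlapping
bins of 16, 32 and 64 px and computes per bin the *fraction of bin pixels
labeled nucleus*, quantized to `Ng = 8` gray levels with fixed absolute
bins on [0, 1] (`level = floor(raw * Ng)` clipped to `Ng - 1`). Two
genuinely open choices were made here:

* *Pixel fraction rather than centroid count per bin.* At 64 px bins many
  nuclei straddle bin borders; the pixel fraction degrades gracefully
  while centroid counting is discontinuous. A centroid-count mode is not
  provided; the raw per-bin fractions are returned alongside the levels
  for anyone wanting different quantization.
* *Absolute rather than per-patch relative quantization* (`mode =
  "absolute"` default, `"relative"` available). Absolute bins make maps
  comparable across patches and patients; relative quantization maximizes
  within-patch contrast but confounds cross-patient comparison.

`Ng = 8` balances texture resolution against co-occurrence sparsity on the
8×8 map of the coarsest scale.

**Haralick features.** `cooccurrence()` builds, per scale, four
symmetrized, normalized gray-level co-occurrence matrices at lattice
distance 1: horizontal (D1), vertical (D2), minor diagonal (D3, 45°), main
diagonal (D4, 135°). `haralick()` computes the canonical 13 statistics
(energy, contrast, correlation, variance, inverse difference moment, sum
average, sum variance, sum entropy, entropy, difference variance,
difference entropy, IMC1, IMC2); the 14th, the maximal correlation
coefficient, is excluded as is conventional. Conventions, fixed and
tested: gray levels indexed by value 0..Ng−1; logarithms base 2 with
`0·log 0 := 0`; sum variance centred on the sum average; correlation and
IMC1 defined as 0 for the degenerate constant map; the IMC2 radicand
clipped at 0. This yields 13 × 4 × 3 = 156 features per patch.

**Aggregation.** `aggregate_slide()` summarizes each patch feature over a
slide's retained patches with mean, median, sample variance (n−1), and
bias-adjusted skewness and excess kurtosis (the G1/G2 sample forms, as in
the common dataframe libraries) — 5 × 13 × 4 = 260 attributes per scale,
named `{stat}_{feature}_{direction}` with the scale tag kept as a separate
schema column (e.g. `var_sum_average_D1`, scale S1 = 16 px). With fewer
than 4 patches the adjusted higher moments are undefined and returned as
NA with a warning rather than silently switching conventions.

## Radiomics: schema, not extraction

CT feature extraction itself (resampling, discretization, the extractor
run) is upstream provenance: this package consumes the resulting table.
`enumerate_radiomics_schema()` pins the canonical 851-name layout of a
default IBSI-style extraction with wavelet filtering: 14 shape features on
the original image plus 93 intensity/texture features (first-order 18,
GLCM 24, GLRLM 16, GLSZM 16, GLDM 14, NGTDM 5) on the original image and
on each of 8 wavelet sub-bands. Shape is geometry of the mask and is not
repeated under filters. `read_radiomics_table()` validates CSVs against
the schema; conformance is advisory (synthetic cohorts use generic names)
while structural problems — missing `patient_id`, duplicate ids,
non-numeric cells — are hard errors.

## Association statistics

All features are z-scored (sample SD; zero-variance columns dropped with a
warning) before any correlation stage.

**Redundancy filter.** `correlation_filter()` implements the mean-absolute-
correlation elimination rule: while any retained pair exceeds |r| = 0.9
(Spearman), the strongest offending pair is examined and the member with
the higher mean absolute correlation against the current survivors is
dropped, recomputing after each elimination. The processing order (largest
|r| first; lexicographic tie-breaks; elimination ties drop the later name)
is fixed purely for determinism — the rule itself does not specify an
order, and an unspecified order makes results irreproducible. The filter
runs per modality, and per scale within pathomics.

**Correlations and endpoints.** `spearman()` is the Pearson correlation of
midranks with the two-sided t-approximation p-value; `cross_correlation()`
computes the full pathomics × radiomics matrix over the inner join of
patients, per-scale sign counts, and a strongest-pairs table (|rho| > 0.5
by default). `endpoint_correlation()` correlates each feature with an
endpoint (pairwise-complete), attaching Benjamini–Hochberg q-values.
Endpoint correlations use observed OS/PFS months and ignore censoring —
a deliberate, documented caveat of rank-correlating survival times; the
synthetic generator can produce administratively censored cohorts to study
the effect of that choice on the >12-month dichotomization.

**KS comparison.** `ks_compare()` computes the two-sample D as the
supremum ECDF gap and the two-sided p-value from the asymptotic Kolmogorov
distribution at `sqrt(n1 n2/(n1+n2)) · D`, evaluated by the theta series
for small arguments and the alternating series otherwise. The asymptotic
(rather than exact) form is used throughout, matching the default of the
common scientific stacks; with feature counts in the dozens-to-hundreds
the difference is immaterial.

## Patient stratification

`hac_cluster()` runs agglomerative clustering — Ward linkage on Euclidean
distances of the z-scored, post-filter feature table — cut at k = 2. Ward
on standardized features is the most common default where no linkage is
otherwise specified; both linkage and metric are arguments, and whether to
cluster on filtered or full features is the caller's choice (the pipeline
uses post-filter features). Labels are canonicalized (cluster 0 = larger;
ties resolved by the lexicographically smallest member id) so output is
invariant to row order. `cluster_summary()` reports, per cluster, the
count and percentage of patients with PFS > 12 months, OS > 12 months, and
CD8 strictly above the cohort median; `compare_assignments()` counts
patients switching clusters between modalities after aligning labels by
the better of the two permutations.

## The synthetic cohort generator

`generate_cohort()` realizes a single-latent-factor model: per patient
`z ~ N(0, 1)` drives (i) tile nucleus rate `260·exp(0.25 z)` per 512 px
tile, (ii) radiomics features `a_j z + N(0, 0.6^2)` with loadings drawn
from a configurable range, and (iii) endpoints `OS = 20·exp(0.5 z + ε)`,
`PFS = 10·exp(0.5 z + ε)` months and
`CD8 = 100·logistic(z − 2.5 + ε)` %, each `ε ~ N(0, 0.25)`. The defaults
emulate a 36-patient immunotherapy cohort: most overall survival above 12
months, progression-free survival mostly below, CD8 centred near 8%.
Nuclei are drawn as non-overlapping dark-purple ellipses (semi-axes 6–10
px, eccentricity ≤ 2:1) on a pale pink background with mild noise, placed
by rejection sampling with a 2 px separation margin — at pixel resolution,
tangent ellipses with zero gap form one connected component and are
"overlapping" for any connected-component analysis, so the margin is part
of what non-overlap *means* here. The palette is fixed so grayscale and
nucleus-channel behaviour is identical across runs.

What the generator does **not** emulate: staining variation, scanner
artifacts, nucleus texture/chromatin structure, spatially clustered (non-
Poisson) nuclei, realistic CT feature distributions or inter-feature
correlation structure beyond one latent factor. Passing recovery tests on
these cohorts therefore demonstrates that the computational chain is
correct and well-calibrated — not that it is robust to real-world slide
and scanner variability.

## Validation strategy and problem sizes

The test suite validates by independent oracles and parameter recovery:

* Haralick statistics against a brute-force loop implementation of the
  defining formulas (100 random GLCMs, max abs difference < 1e-8), and
  against scikit-image's `graycoprops` for the four shared statistics.
* Co-occurrence counting against explicit pair enumeration.
* Spearman/Benjamini–Hochberg/KS against hand-computed small cases.
* Segmentation against generator ground truth: exact nucleus counts on
  ≥95% of 200 seeded tiles (256 px, ~65 nuclei each; in practice the rate
  is ~100%).
* Cross-modal recovery: on 200-patient cohorts (one 256 px tile per
  patient, loadings spanning ±0.8, noise SD 0.6) the estimated
  pathomics–radiomics Spearman profile correlates > 0.9 across features
  with the loadings' implied correlations (observed ~0.99). Two seeded
  replicates run in the suite; the tabular KS-discrimination study uses 30
  replicates per condition (60 features per modality), with observed
  reject/retain rates at or near 100% against the ≥80% requirement.
* Redundancy filtering against hand-derived eliminations plus a
  post-condition sweep (no retained pair above threshold) on 20 random
  50-column tables.
* Clustering against planted two-blob partitions and brute-force summary
  counting.

These sizes were chosen so the whole suite runs in a few minutes on one
CPU while keeping every recovery margin wide; they are stated here so a
reader knows exactly what was demonstrated at which n.

## Known limitations

* Tissue masking is slide-scale by construction (see above); there is no
  stain normalization or pen/blur artifact detection beyond the stated
  morphology steps.
* The global sure-foreground threshold (`fg_frac`·max distance) can miss
  markers for nuclei much smaller than the largest one in a patch; with
  the generator's 6–10 px semi-axes every nucleus clears the default
  threshold, but heterogeneous real material may warrant per-component
  thresholds.
* Endpoint correlations ignore censoring, and no survival modeling
  (Cox, Kaplan–Meier, log-rank) is provided — the stratification output is
  descriptive proportions only.
* Nucleus categories (size/shape) are metadata and feed no downstream
  statistic.
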