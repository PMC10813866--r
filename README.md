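# radiopathomics

Cross-scale association analysis between CT radiomics and cell-density
pathomics features for small oncology cohorts, built for the setting of
immunotherapy-treated non-small cell lung cancer where both a pre-treatment
CT feature table and digitized H&E histology are available per patient.

The package covers the complete chain:

* **Histology preprocessing** — tissue masking (grayscale → Otsu → dilation →
  hole filling → small-object removal), non-overlapping 512 px grid patch
  extraction with a ≥80% tissue rule, and a nucleus-score filter that keeps
  patches whose nucleus-pixel fraction is ≥15%.
* **Nucleus density maps** — marker-controlled watershed segmentation of
  nuclei (hematoxylin-channel classification, distance transform, threshold
  markers), then per-patch cell-density maps at 16/32/64 px bins, quantized
  to 8 gray levels.
* **Pathomics features** — four directional gray-level co-occurrence
  matrices per density map and the 13 classic Haralick statistics:
  13 × 4 directions × 3 scales = 156 features per patch, aggregated to the
  slide level with mean/median/variance/kurtosis/skewness = 260 attributes
  per scale.
* **Radiomics I/O** — the canonical 851-name CT feature schema (original +
  8 wavelet sub-bands × first-order and five texture families, shape on the
  original only) with CSV ingestion and validation; CT extraction itself is
  upstream and out of scope.
* **Association statistics** — z-scoring, the |r| > 0.9 Spearman redundancy
  filter (mean-absolute-correlation elimination), full cross-modal Spearman
  matrices with per-scale sign counts, per-endpoint (OS, PFS, CD8)
  correlations with Benjamini–Hochberg FDR, and two-sample
  Kolmogorov–Smirnov comparison of the two modalities' correlation
  distributions.
* **Patient stratification** — Ward/Euclidean hierarchical clustering cut at
  two clusters per modality, cluster summaries (PFS > 12 months,
  OS > 12 months, CD8 above the cohort median), and cluster-switch counts
  between modalities.
* **Synthetic cohorts** — a seeded generator in which one latent factor per
  patient drives tile nucleus density, radiomics loadings and clinical
  endpoints, so every stage is testable by parameter recovery without any
  private patient data.

The central statistic throughout is Spearman's rank correlation
ρ = cor(rank x, rank y); distribution-level contrasts use the two-sample KS
statistic D = sup_t |F̂_a(t) − F̂_b(t)| with the asymptotic Kolmogorov
p-value at √(n₁n₂/(n₁+n₂))·D.

## Worked example

```r
library(radiopathomics)

spec <- synthetic_cohort_spec(n_patients = 12, n_tiles_per_patient = 2,
                              tile_size = 256, nuclei_rate_base = 90,
                              seed = 42)
cfg <- run_config(cohort_spec = spec, seed = 42)
res <- suppressWarnings(run_pipeline(cfg))

res$ks$pfs
#> two-sample KS: D = 0.623, p = 0 (n = 91, 204)

res$cluster_summaries$pathomics
#>   cluster size pfs_gt_cutoff pfs_pct os_gt_cutoff os_pct cd8_gt_median
#> 1       0   10             7      70           10    100             6
#> 2       1    2             1      50            2    100             0
#>   cd8_pct_gt_median
#> 1                60
#> 2                 0

head(res$cross$top_pairs, 3)
#>   radiomics_feature             pathomics_feature        rho scale_px
#> 1              f007        mean_sum_average_D1_S2  0.9650350       32
#> 2              f007        mean_sum_average_D3_S3  0.9632239       64
#> 3              f044 mean_difference_entropy_D4_S1 -0.9580420       16
```

Reading the output: the pipeline retained 204 of 780 pathomics and 91 of
100 radiomics features after the |r| > 0.9 redundancy filter. The KS line
compares the distribution of the 91 radiomics-vs-PFS Spearman coefficients
against the 204 pathomics-vs-PFS coefficients; in this planted cohort both
modalities load on the same latent factor but with different coupling
shapes, so the distributions differ sharply (D = 0.62). The cluster summary
is the standard stratification table: cluster 0 holds 10 of 12 patients, of
whom 70% progressed later than 12 months and 60% sit above the cohort CD8
median. The strongest cross-modal pairs recover the planted structure —
slide-level mean sum-average (a monotone readout of nucleus density) tracks
the radiomics features with the largest latent loadings at |ρ| ≈ 0.96.
`res$switches$switched` reports how many patients change cluster when moving
from pathomics to radiomics features (5 here, after label alignment).

A thin CLI over the same functions supports `simulate`, `features`,
`associate`, `cluster` and `run-all` subcommands:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "radiopath.R",
                                      package = "radiopathomics"))') \
    run-all --seed 1 --patients 36 --out run_dir
```

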