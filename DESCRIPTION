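Package: radiopathomics
Title: Cross-Scale Association of CT Radiomics and Cell-Density Pathomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to relate quantitative features of routine CT imaging
    (radiomics) to texture features of cell-density maps computed from
    H&E histology tiles (pathomics) in small oncology cohorts, with a focus
    on immunotherapy-treated non-small cell lung cancer. Provides tissue
    masking and patch extraction for whole-slide imagery, watershed nucleus
    segmentation, multi-scale quantized cell-density maps, directional
    gray-level co-occurrence matrices with the 13 classic Haralick texture
    statistics, slide-level feature aggregation, a canonical CT radiomics
    feature-name schema, Spearman redundancy filtering, cross-modal and
    clinical-endpoint correlation with false-discovery-rate control,
    Kolmogorov-Smirnov comparison of correlation distributions, two-cluster
    hierarchical patient stratification, and a seeded synthetic-cohort
    generator with planted latent structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
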