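Package: pdfftexture
Title: Texture Analysis of Muscle Proton Density Fat Fraction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: First- and second-order texture analysis of quantitative
    water-fat MRI proton density fat fraction (PDFF) maps of paraspinal
    muscle, as used to relate muscle fat-infiltration patterns to isometric
    strength. Implements histogram (global) features with a
    median-of-three bin rule, rotation-invariant 3D gray-level
    co-occurrence matrix (GLCM) features over 13 directions after
    isotropic resampling and uniform quantization, volume-weighted
    bilateral aggregation, and the cohort statistics layer
    (Kolmogorov-Smirnov screening, pooled t-tests, Bonferroni-corrected
    Pearson screens, and stepwise multivariate regression driven by
    partial F-tests). A synthetic phantom and cohort generator with
    controllable fatty-streak heterogeneity supports end-to-end testing
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
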