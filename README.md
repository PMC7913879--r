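# pdfftexture

Texture analysis of quantitative water–fat MRI proton density fat fraction
(PDFF) maps of paraspinal muscle, and the statistics that relate texture to
isometric muscle strength.

Mean PDFF of a segmented muscle measures *how much* fat it contains;
texture features measure *how that fat is arranged*. A muscle with diffuse
homogeneous infiltration and one with focal fatty streaks can share a mean
PDFF yet differ sharply in function. `pdfftexture` is for researchers in
quantitative muscle imaging who want that pattern quantified and related
to outcomes:

* **PDFF maps and ROIs** — NIfTI I/O, `PDFF = 100·F/(F+W)` % from
  fat/water signal volumes, ROI extraction with physical volumes.
* **First-order (global) features** — variance, skewness and non-excess
  kurtosis of the in-mask intensity histogram, with the bin count chosen
  as the median of Sturges', Scott's and Freedman–Diaconis' rules.
* **Second-order features** — 3D gray-level co-occurrence matrices (GLCM)
  built after isotropic resampling and 200-level uniform quantization,
  from the 26 lattice neighbours in 13 directions; energy, entropy,
  contrast, homogeneity, correlation, variance, sum average and
  dissimilarity, averaged over directions for rotation invariance.
* **Bilateral aggregation** — right/left features combined per muscle
  group, weighted by physical muscle volume.
* **Cohort statistics** — Kolmogorov–Smirnov normality screening,
  pooled-variance sex comparisons, Bonferroni-corrected Pearson
  correlation screens (α/24 = 0.0021 for the 24-variable strength
  family), and bidirectional stepwise linear regression driven by partial
  F-tests (entry p < 0.05, removal p > 0.10) with adjusted R².
* **Synthetic phantoms and cohorts** — elliptic-cylinder muscle phantoms
  with controllable fatty-streak heterogeneity and full cohorts with
  strength outcomes planted on texture features, so every stage is
  testable without patient data.

## Worked example

Generate a synthetic cohort through the real feature pipeline, screen
texture features against extension strength, and fit the stepwise model:

```r
library(pdfftexture)

co <- generate_cohort(cohort_config(n_subjects = 26, seed = 42))
co
#> <pdff_cohort> 26 subjects, 15 female
#>   planted: mvic_ext ~ kurtosis_global_es + bmi; mvic_flex ~ variance_global_ps + skewness_global_ps

scr <- correlation_screen(co$cohort, "mvic_ext", m = 24)
head(as.data.frame(scr[, c("variable", "r", "p_value", "significant")]), 3)
#>             variable       r   p_value significant
#> 1 kurtosis_global_es  0.6305 0.0005543        TRUE
#> 2 skewness_global_es  0.6112 0.0009107        TRUE
#> 3   dissimilarity_es -0.4926 0.0105712       FALSE

m <- stepwise_regression(co$cohort, "mvic_ext")
m
#> Stepwise linear model for mvic_ext
#>   selected: kurtosis_global_es, bmi, contrast_ps
#>   R^2 = 0.825, adjusted R^2 = 0.801, n = 26
tidy(m)
#> # A tibble: 4 × 5
#>   term               estimate std_error statistic     p_value
#>   <chr>                 <dbl>     <dbl>     <dbl>       <dbl>
#> 1 (Intercept)        -28.2      30.4       -0.927 0.364
#> 2 kurtosis_global_es   6.12      0.862      7.10  0.000000399
#> 3 bmi                  7.03      1.01       6.96  0.000000551
#> 4 contrast_ps         -0.0405    0.0138    -2.93  0.00775
```

The correlation screen reports Pearson r per feature with Bonferroni flags
at α/m; only the planted texture feature (and its correlated sibling)
survive the corrected level 0.0021, while weaker correlations do not. The
stepwise model recovers the planted predictors — the texture feature and
BMI, not mean PDFF — with coefficients near the generating values (6.12 vs
7 and 7.03 vs 8); at n = 26 a spurious third term slips in at p = 0.008,
which is exactly the small-sample behaviour p-value stepwise is known for.

Per-muscle feature extraction on real data follows the same surface:

```r
pdff <- read_volume("pdff.nii.gz")
mask <- read_mask("es_right.nii.gz", muscle = "ES", side = "right")
texture_profile(pdff, mask)            # one row: mean PDFF + 11 features
```

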