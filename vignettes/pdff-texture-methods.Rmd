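---
title: "Texture analysis of muscle PDFF maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of muscle PDFF maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdfftexture)
```

## The problem

Chemical-shift-encoding water–fat MRI yields voxelwise proton density fat
fraction (PDFF) maps: `PDFF = 100 * F / (F + W)` percent, where `F` and `W`
are the fat and water signal magnitudes. In paraspinal muscle (erector
spinae, ES; psoas, PS) the *mean* PDFF of a segmented muscle summarises fat
content but discards the spatial pattern of fatty infiltration — a muscle
with diffuse, homogeneous infiltration and one riddled with focal fatty
streaks can share the same mean. Texture analysis quantifies that pattern:
first-order features describe the shape of the intensity distribution, and
second-order (co-occurrence) features describe its spatial arrangement.
Those features can then be related to functional outcomes such as maximum
voluntary isometric torque (MVIC, Nm) of trunk extension and flexion.

`pdfftexture` implements that full analysis chain — map construction, ROI
extraction, preprocessing, the eleven texture features, volume-weighted
bilateral aggregation, and the cohort statistics layer — together with a
synthetic phantom/cohort generator so that every stage is testable without
patient data.

## Feature definitions

**First-order (global) features.** The in-mask voxel values are binned into
an equal-width histogram whose bin count is the median of Sturges'
(`ceiling(log2 n) + 1`), Scott's (`h = 3.49 s n^{-1/3}`) and
Freedman–Diaconis (`h = 2 IQR n^{-1/3}`) rules. With bin centres `c_k` and
probabilities `p_k`, and `mu = sum(p_k c_k)`:

* `variance_global = m2 = sum(p_k (c_k - mu)^2)` (percent²),
* `skewness_global = m3 / m2^{3/2}`,
* `kurtosis_global = m4 / m2^2` — non-excess, so a normal distribution
  gives 3.

Degenerate conventions: a zero-range sample occupies a single bin; a
zero-variance histogram reports skewness and kurtosis 0 with a degeneracy
flag. The Freedman–Diaconis quartiles use linear interpolation between
order statistics (`stats::quantile` type 7); a zero IQR with positive range
falls back to the Sturges count, and a zero range to one bin.

**Second-order (GLCM) features.** The gray-level co-occurrence matrix at
displacement `d` counts in-mask voxel pairs `(v, v + d)`, is symmetrised
with its transpose and normalised to a joint probability `p(i, j)`. With
marginal mean `mu` and variance `sigma^2` (row marginal of the symmetric
matrix):

| feature | formula |
|---|---|
| energy | `sum p^2` |
| entropy | `-sum p log2 p` (bits) |
| contrast | `sum (i-j)^2 p` |
| homogeneity | `sum p / (1 + |i-j|)` |
| correlation | `sum (i-mu)(j-mu) p / sigma^2` |
| variance | `sum (i-mu)^2 p` |
| sum average | `sum_k k p_{x+y}(k)` |
| dissimilarity | `sum |i-j| p` |

Correlation is defined as 0 (flagged) when `sigma^2 = 0`, where the
classical definition is indeterminate. The entropy logarithm base is
configurable (`entropy_log_base`); base 2 is the default.

**Rotation invariance.** On a 3D lattice every voxel has 26 neighbours
falling into 13 direction pairs under sign inversion; because the GLCM is
symmetric, one representative per pair suffices. Features are computed per
direction and averaged with equal weights over the non-degenerate
directions. Directions whose offset admits no in-mask pair are skipped and
reported.

## Preprocessing choices

Anisotropic voxels (the reference protocol uses 3.2 × 2.0 × 4.0 mm³) make
the 13 offsets physically incomparable, so GLCM analysis runs on an
isotropically resampled grid whose target edge is the minimum input
spacing (no axis is downsampled; 2.0 mm for the reference protocol). We
honour "discretisation length differences" this way rather than by
per-direction distance weighting, which is available behind a flag but off
by default. Intensities are interpolated trilinearly in a mask-weighted
(normalised-convolution) form: the interpolants of `v * m` and of the
binary mask `m` are divided, so boundary voxels average in-mask neighbours
only instead of blending in background zeros — without this, a perfectly
homogeneous muscle would acquire spurious edge texture. The mask itself is
thresholded at interpolated weight ≥ 0.5, which reduces to
nearest-neighbour assignment at on-grid points.

Gray levels are quantized uniformly into `Ng = 200` bins between the
minimum and maximum level present *in the ROI* (the default); the clause
"minimum and maximum gray levels present" admits a fixed 0–100 % reading,
which is available via `quantize(bounds = "fixed")`. A constant ROI maps
to level 1 everywhere. A range at floating-point noise level (≤ 1e-9
relative) is treated as constant.

Global features are computed from the original-resolution in-mask voxels,
before any resampling: the histogram features carry physical percent units
and need no lattice, whereas resampling is a GLCM-specific preprocessing
step. Whether first-order features should instead be computed after
resampling is genuinely ambiguous; computing them on native voxels avoids
interpolation-induced smoothing of the distribution's tails, to which
kurtosis is very sensitive.

## Bilateral aggregation and the cohort table

Right and left features of a muscle group are combined as
`f = (f_R V_R + f_L V_L) / (V_R + V_L)` with `V` the physical muscle
volume in mm³ (resolution-independent, unlike voxel counts), applied
identically to mean PDFF and all 11 texture features. The per-subject
cohort table carries 26 candidate predictors — age, BMI, bilateral mean
PDFF of ES and PS, and the 22 bilateral texture features — plus sex and
the two torque outcomes.

## Statistics layer

* `ks_normality()`: one-sample Kolmogorov–Smirnov test against a normal
  with sample-estimated mean and SD. With estimated parameters the
  asymptotic p-value is anticonservative; the function documents this and
  is intended as the conventional screen, not an exact test.
* `sex_compare()` / `cohort_sex_table()`: two-sided pooled-variance
  (Student) unpaired t-tests. The pooled variant (not Welch) is the
  classical default of the major statistics packages; it is recorded as a
  deliberate choice.
* `correlation_screen()`: Pearson r with exact t-based two-sided p-values,
  flagged at the Bonferroni level `alpha / m`. The family size `m` is an
  explicit argument (24 for the strength screen: 2 mean PDFF + 22 texture
  features) because the appropriate family for the sex-difference table is
  ambiguous between 22 and 24.
* `stepwise_regression()`: bidirectional p-value-driven selection with
  partial F-tests, entry at `p < 0.05` and removal at `p > 0.10`. Base R's
  `step()` is AIC-based, so the entry/removal loop is implemented here on
  top of `lm()`. Ties break on the smaller p, then alphabetically; a
  visited-state set guards against entry/removal cycles; once the fit is
  numerically exact (RSS below 1e-10 of the outcome's total sum of
  squares) entry stops, so the noiseless limit returns exactly the planted
  predictors. If nothing qualifies the intercept-only model is returned.
* `adjusted_r2()`: `1 - (1 - R^2)(n - 1)/(n - k - 1)`.

## The synthetic generator

`generate_phantom()` builds one muscle as an elliptic cylinder (axis
cranio-caudal) on the anisotropic grid, filled with a clipped-normal base
PDFF field plus `n_streaks` prolate ellipsoidal fatty streaks elongated
along the cranio-caudal axis, placed uniformly at in-mask centres. Streaks
blend into the base field with weight `1 - r^2` (full streak PDFF at the
core, base at the boundary), emulating partial-volume gradation at
multi-millimetre voxels; with hard-edged streaks the generator produced
two-point mixtures with kurtosis an order of magnitude above anything seen
in muscle. The generator can also emit consistent fat/water signal
volumes, so `compute_pdff()` is exercised end-to-end.

`generate_cohort()` draws, per subject: sex (fixed census, 15/26 female by
default), age (30.27 ± 6.12 y), BMI (27.01 ± 2.69 kg/m²), a sex-specific
base PDFF level per muscle (chosen so the realized bilateral means land on
the reference values — ES ≈ 10.5 %, higher in females; PS ≈ 4.8 %), and
two *independent* heterogeneity draws: the streak count per muscle side
(Poisson; ES 6, PS 3) and the subject's streak PDFF centre (uniform
55–85 %). Count and intensity drive within-ROI variance and tail position
differently, so the two planted flexion predictors (variance and skewness)
are correlated only weakly across subjects — by construction, not by
tuning. Features are extracted through the *real* pipeline, and torques
are then generated from declared linear models on the realized features:

* `mvic_ext = -90 + 7 * kurtosis_global_es + 8 * bmi + N(0, 15)`,
* `mvic_flex = 83 + 0.55 * variance_global_ps + 12 * skewness_global_ps +
  N(0, 10)`,

with coefficients fixed once so that generated torques span roughly
100–340 Nm. The planted coefficients and per-subject heterogeneity are
returned as ground truth for recovery testing.

**What the generator does not emulate:** MR physics (echoes, field maps,
T1/T2* bias), realistic muscle anatomy, intermuscular fascia, segmentation
error, or left/right asymmetry (sides share parameters and differ only by
independent noise). Passing recovery tests on this generator shows the
pipeline's statistical machinery is sound at realistic effect sizes; it
does not validate the features against histology or against other
radiomics implementations on real data.

## Problem sizes and numerical conventions

Phantoms default to 13 × 17 × 12 (ES) and 9 × 13 × 12 (PS) voxel grids —
about 1700 and 900 in-mask voxels — which keeps a full four-muscle subject
near 0.1 s and makes repeated-cohort studies (50 cohorts of n = 100)
practical on one core; the recovery properties tested are size-stable.
Oracle equivalence for the GLCM path is checked against brute-force pair
enumeration on grids up to 8³ with up to 6 levels, where exhaustive
enumeration is exact and fast. Histogram-moment equivalence uses fine
binning (centres converge to the sample values). All equality tolerances
on oracle comparisons are 1e-12; geometric identities (round trips, axis
swaps) are exact or 1e-10.

## Known limitations

* The KS screen with estimated parameters is anticonservative; a
  Lilliefors-corrected variant would be stricter.
* Histogram-based moments depend on the bin rule; with few bins kurtosis
  is biased low relative to raw sample moments. The median-of-three rule
  makes this reproducible but not rule-free.
* GLCM features are reported on the quantized-level scale and depend on
  `Ng` and on the ROI-extrema normalisation; cross-study comparability
  requires identical settings.
* Stepwise p-value selection inherits the classical caveats (inflated
  in-sample R², post-selection inference); it is implemented faithfully as
  the reference procedure, not endorsed as best practice.
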