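#' Names of the eleven texture features
#'
#' Three first-order (global) histogram features and eight direction-averaged
#' GLCM features, in the canonical column order used throughout the package.
#'
#' @return Character vector of length 11.
#' @export
feature_names <- function() {
  c("variance_global", "skewness_global", "kurtosis_global",
    "energy", "entropy", "contrast", "homogeneity", "correlation",
    "variance", "sum_average", "dissimilarity")
}

#' Full texture profile of one muscle ROI
#'
#' Runs the complete per-muscle pipeline on a PDFF map and its mask:
#' * mean PDFF and physical volume from the original-grid in-mask voxels;
#' * the three global features from the intensity histogram of those voxels
#'   (bin count by the median-of-three rule unless overridden);
#' * the eight GLCM features from the isotropically resampled, uniformly
#'   quantized ROI, averaged over the 13 lattice directions.
#'
#' @param volume A PDFF [volume_grid()] (percent scale).
#' @param mask A paired non-empty [roi_mask()].
#' @param ng_levels Gray levels for quantization (default 200).
#' @param histogram_rule `"median3"` (default), `"sturges"`, `"scott"` or
#'   `"fd"`; rule for the global-feature histogram bin count.
#' @param isotropic_target `"min"` or a fixed edge in mm, passed to
#'   [resample_isotropic()].
#' @param quantize_bounds `"roi"` or `"fixed"`, passed to [quantize()].
#' @param entropy_log_base Base for GLCM entropy (default 2, bits).
#' @return A one-row tibble: `muscle`, `side`, `voxel_count`, `volume_mm3`,
#'   `mean_pdff`, the 11 features of [feature_names()], `degenerate`,
#'   `n_skipped_directions`.
#' @export
texture_profile <- function(volume, mask, ng_levels = 200,
                            histogram_rule = c("median3", "sturges",
                                               "scott", "fd"),
                            isotropic_target = "min",
                            quantize_bounds = "roi",
                            entropy_log_base = 2) {
  histogram_rule <- match.arg(histogram_rule)
  roi <- extract_roi(volume, mask)
  vals <- roi$voxel_values

  k <- if (length(vals) < 2L) 1L else switch(histogram_rule,
    median3 = select_bin_count(vals),
    sturges = bins_sturges(length(vals)),
    scott = bins_scott(vals),
    fd = bins_freedman_diaconis(vals))
  glob <- global_features(build_histogram(vals, k))

  iso <- resample_isotropic(volume, mask, target = isotropic_target)
  q <- quantize(iso$volume, iso$mask, ng = ng_levels,
                bounds = quantize_bounds)
  dirs <- glcm_directions()
  per_dir <- lapply(seq_len(nrow(dirs)), function(r) {
    g <- build_glcm(q, dirs[r, ])
    if (g$skipped) NULL else glcm_features_num(g, entropy_log_base)
  })
  kept <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (length(kept) == 0L) {
    stop_pdff("all directions were skipped; ROI too small for GLCM.",
              "pdff_degenerate_roi_error")
  }
  avg <- colMeans(do.call(rbind, kept))
  glcm <- as.list(avg[glcm_feature_names()])
  glcm$degenerate <- avg[["degenerate"]] > 0
  glcm$n_skipped <- length(per_dir) - length(kept)

  tibble(muscle = roi$muscle, side = roi$side,
         voxel_count = roi$voxel_count, volume_mm3 = roi$physical_volume,
         mean_pdff = mean(vals),
         variance_global = glob$variance_global,
         skewness_global = glob$skewness_global,
         kurtosis_global = glob$kurtosis_global,
         energy = glcm$energy, entropy = glcm$entropy,
         contrast = glcm$contrast, homogeneity = glcm$homogeneity,
         correlation = glcm$correlation, variance = glcm$variance,
         sum_average = glcm$sum_average, dissimilarity = glcm$dissimilarity,
         degenerate = glob$degenerate | glcm$degenerate,
         n_skipped_directions = glcm$n_skipped)
}
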