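# Per-axis interpolation support: fractional source positions for target
# voxel centres at spacing s_new over an axis of n_old voxels at s_old.
# Voxel centres sit at (i-1)*s (origin at the first centre); target centres
# never extrapolate beyond the last source centre.
axis_positions <- function(n_old, s_old, s_new) {
  n_new <- max(1L, as.integer(floor((n_old - 1) * s_old / s_new)) + 1L)
  p <- (seq_len(n_new) - 1) * s_new / s_old       # 0-based fractional index
  i0 <- pmax(pmin(floor(p), n_old - 2), 0)
  list(n = n_new, lo = as.integer(i0) + 1L, t = p - i0)
}

# Vectorised trilinear interpolation: 8-corner gather with outer-product
# weights. ax/ay/az come from axis_positions().
trilinear <- function(vol, ax, ay, az) {
  d <- dim(vol)
  acc <- array(0, c(ax$n, ay$n, az$n))
  for (a in 0:1) {
    wx <- if (a == 0) 1 - ax$t else ax$t
    ix <- pmin(ax$lo + a, d[1])
    for (b in 0:1) {
      wy <- if (b == 0) 1 - ay$t else ay$t
      iy <- pmin(ay$lo + b, d[2])
      for (cc in 0:1) {
        wz <- if (cc == 0) 1 - az$t else az$t
        iz <- pmin(az$lo + cc, d[3])
        w <- outer(outer(wx, wy), wz)
        if (any(w > 0)) acc <- acc + w * vol[ix, iy, iz, drop = FALSE]
      }
    }
  }
  acc
}

#' Resample a volume and its mask to isotropic voxels
#'
#' Regrids both the intensity volume and its binary mask to cubic voxels.
#' The default target edge is the smallest input spacing, so no axis is
#' downsampled. Intensities are interpolated trilinearly; the mask is
#' interpolated as a 0/1 field and thresholded at >= 0.5 (which reduces to
#' nearest-neighbour at on-grid points). GLCM analysis runs on this grid so
#' that all 13 unit-voxel offsets have comparable physical length.
#'
#' @param volume A [volume_grid()].
#' @param mask An [roi_mask()] paired with `volume`.
#' @param target Either `"min"` (edge = smallest input spacing) or a single
#'   positive number, the target edge in mm.
#' @return List with elements `volume` and `mask`, both isotropic.
#' @export
resample_isotropic <- function(volume, mask, target = "min") {
  check_paired(volume, mask)
  s_new <- if (identical(target, "min")) min(volume$spacing)
           else as.numeric(target)
  if (length(s_new) != 1L || is.na(s_new) || s_new <= 0) {
    stop_pdff("`target` must be \"min\" or a positive edge length in mm.",
              "pdff_config_error")
  }
  d <- dim(volume$values)
  ax <- axis_positions(d[1], volume$spacing[1], s_new)
  ay <- axis_positions(d[2], volume$spacing[2], s_new)
  az <- axis_positions(d[3], volume$spacing[3], s_new)
  # mask-weighted (normalised-convolution) interpolation: background
  # voxels carry no intensity information, so interpolate v*m and m and
  # divide — boundary voxels then average in-mask neighbours only instead
  # of blending in background zeros
  mw <- trilinear(mask$values, ax, ay, az)
  vals <- trilinear(volume$values * mask$values, ax, ay, az)
  pos <- mw > 0
  vals[pos] <- vals[pos] / mw[pos]
  vals[!pos] <- 0
  mvals <- (mw >= 0.5) * 1
  if (sum(mvals) == 0) {
    stop_pdff("mask is empty after isotropic resampling.",
              "pdff_empty_roi_error")
  }
  list(volume = volume_grid(vals, spacing = rep(s_new, 3),
                            origin = volume$origin),
       mask = roi_mask(mvals, muscle = mask$muscle, side = mask$side,
                       spacing = rep(s_new, 3)))
}

#' Uniform gray-level quantization of an ROI
#'
#' Maps in-mask intensities onto `ng` equally sized bins between the minimum
#' and maximum gray level present in the ROI (the default; fixed 0--100 %
#' bounds are available via `bounds = "fixed"`):
#' `level(v) = min(floor((v - vmin) / (vmax - vmin) * ng) + 1, ng)`.
#' A constant ROI maps entirely to level 1. Out-of-mask voxels get level 0.
#'
#' @param volume A [volume_grid()] (PDFF in percent for `bounds = "fixed"`).
#' @param mask Paired non-empty [roi_mask()].
#' @param ng Number of gray levels, default 200.
#' @param bounds `"roi"` (in-mask extrema) or `"fixed"` (0 and 100 %).
#' @return A `quantized_roi`: list with integer array `levels` (0 outside
#'   the mask), `ng`, `mask`, `spacing`.
#' @examples
#' v <- volume_grid(array(c(0, 25, 50, 75, 100, 0, 0, 0), c(2, 2, 2)),
#'                  c(1, 1, 1))
#' m <- roi_mask(array(c(1, 1, 1, 1, 1, 0, 0, 0), c(2, 2, 2)))
#' q <- quantize(v, m, ng = 4)
#' q$levels[m$values == 1]  # 1 2 3 4 4
#' @export
quantize <- function(volume, mask, ng = 200, bounds = c("roi", "fixed")) {
  check_paired(volume, mask)
  bounds <- match.arg(bounds)
  if (length(ng) != 1L || is.na(ng) || ng < 1) {
    stop_pdff("`ng` must be a single level count >= 1.", "pdff_config_error")
  }
  ng <- as.integer(ng)
  keep <- mask$values == 1
  if (!any(keep)) {
    stop_pdff("mask contains no foreground voxels.", "pdff_empty_roi_error")
  }
  v <- volume$values[keep]
  if (bounds == "roi") {
    vmin <- min(v)
    vmax <- max(v)
  } else {
    vmin <- 0
    vmax <- 100
  }
  lv <- array(0L, dim(volume$values))
  # a range at floating-point noise level (e.g. after interpolating a
  # constant field) is treated as constant
  if (vmax - vmin <= 1e-9 * max(abs(vmax), abs(vmin), 1)) {
    lv[keep] <- 1L
  } else {
    lv[keep] <- as.integer(pmin(floor((v - vmin) / (vmax - vmin) * ng) + 1,
                                ng))
  }
  structure(list(levels = lv, ng = ng, mask = mask, spacing = volume$spacing),
            class = "quantized_roi")
}
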