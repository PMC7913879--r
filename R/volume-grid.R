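#' Volumetric scalar grid with physical voxel spacing
#'
#' `volume_grid()` wraps a 3D numeric array together with its voxel spacing
#' (mm per axis) and a physical origin. It is the in-memory representation of
#' a PDFF map (percent scale, 0--100) or of a raw fat/water signal volume.
#' No reorientation is ever applied: masks must live on the same grid as the
#' map they index, mirroring segmentation performed directly on the PDFF maps.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm; all `> 0`.
#' @param origin Numeric length-3, physical position of the first voxel
#'   centre in mm.
#'
#' @return A `volume_grid` object (list with `values`, `spacing`, `origin`).
#' @examples
#' v <- volume_grid(array(0, c(4, 4, 2)), spacing = c(3.2, 2.0, 4.0))
#' voxel_volume(v)  # 25.6 mm^3
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  d <- dim(values)
  if (!is.numeric(unclass(values)) || length(d) != 3L) {
    stop_pdff("`values` must be a 3D numeric array.", "pdff_format_error")
  }
  # plain array, shedding any foreign attributes (e.g. image headers)
  values <- array(as.double(values), dim = d)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0)) {
    stop_pdff("`spacing` must be 3 strictly positive voxel sizes (mm).",
              "pdff_format_error")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) {
    stop_pdff("`origin` must have length 3.", "pdff_format_error")
  }
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  rng <- range(x$values)
  cat("  value range [", format(rng[1]), ", ", format(rng[2]), "]\n", sep = "")
  invisible(x)
}

#' Physical volume of one voxel in mm^3
#' @param volume A [volume_grid()] or [roi_mask()].
#' @return Scalar, `prod(spacing)` in mm^3.
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

#' Binary region-of-interest mask for one muscle
#'
#' A mask is a 0/1 array on the same grid (shape and spacing) as the volume
#' it indexes, labelled with the muscle group (erector spinae `"ES"` or psoas
#' `"PS"`) and body side.
#'
#' @param values 3D array coercible to 0/1.
#' @param muscle `"ES"` or `"PS"`.
#' @param side `"right"` or `"left"`.
#' @param spacing Voxel spacing in mm, identical to the paired volume.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(values, muscle = c("ES", "PS"),
                     side = c("right", "left"), spacing = c(1, 1, 1)) {
  muscle <- match.arg(muscle)
  side <- match.arg(side)
  values <- unclass(values)
  if (!is.numeric(values) || length(dim(values)) != 3L) {
    stop_pdff("mask `values` must be a 3D numeric array.", "pdff_format_error")
  }
  if (!all(values %in% c(0, 1))) {
    stop_pdff("mask values must be binary (0 background, 1 foreground).",
              "pdff_format_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_pdff("`spacing` must be 3 strictly positive voxel sizes (mm).",
              "pdff_format_error")
  }
  structure(list(values = values, muscle = muscle, side = side,
                 spacing = spacing),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", x$muscle, " ", x$side, ", ",
      sum(x$values), " foreground voxels of ",
      paste(dim(x$values), collapse = " x "), "\n", sep = "")
  invisible(x)
}

# Shared precondition: mask paired with volume (same shape and spacing).
check_paired <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values))) {
    stop_pdff("volume and mask shapes differ.", "pdff_alignment_error")
  }
  if (!isTRUE(all.equal(volume$spacing, mask$spacing))) {
    stop_pdff("volume and mask spacings differ.", "pdff_alignment_error")
  }
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file with exactly 3 spatial
#'   dimensions and strictly positive voxel sizes.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    stop_pdff(paste0("file not found: ", path), "pdff_format_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_pdff("NIfTI image must have exactly 3 spatial dimensions.",
              "pdff_format_error")
  }
  spacing <- abs(RNifti::pixdim(img))
  if (length(spacing) < 3L || any(spacing[1:3] <= 0)) {
    stop_pdff("NIfTI header has non-positive voxel sizes.",
              "pdff_format_error")
  }
  orig <- tryCatch(-RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  volume_grid(arr, spacing = spacing[1:3], origin = orig)
}

#' Write a volume to NIfTI
#'
#' Writes NIfTI-2 by default so that voxel sizes survive the round trip at
#' full double precision (NIfTI-1 stores `pixdim` as 32-bit float).
#'
#' @param volume A [volume_grid()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param version NIfTI version, 1 or 2.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, version = 2) {
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, version = version)
  invisible(path)
}

#' Read a binary muscle mask from NIfTI
#'
#' Mask files are integer-valued. Either a plain 0/1 file, or a labelled file
#' from which one label is extracted (e.g. the convention 1 = ES right,
#' 2 = ES left, 3 = PS right, 4 = PS left).
#'
#' @param path NIfTI file.
#' @inheritParams roi_mask
#' @param label Optional integer; voxels equal to `label` become foreground.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, muscle, side, label = NULL) {
  vol <- read_volume(path)
  vals <- vol$values
  if (!is.null(label)) {
    vals <- (vals == label) * 1
  }
  roi_mask(vals, muscle = muscle, side = side, spacing = vol$spacing)
}

#' Proton density fat fraction from fat and water signal volumes
#'
#' PDFF is the ratio of the fat signal over the sum of fat and water signals,
#' on the percent scale: `100 * F / (F + W)`. Voxels with zero total signal
#' (air background) are defined as 0 % and counted; the tally is attached as
#' attribute `"n_degenerate"` so mask leakage into background is visible.
#'
#' @param fat,water [volume_grid()]s of non-negative signal, same shape and
#'   spacing.
#' @return A PDFF [volume_grid()] in percent with attribute `n_degenerate`.
#' @examples
#' f <- volume_grid(array(1, c(2, 2, 2)), c(1, 1, 1))
#' w <- volume_grid(array(3, c(2, 2, 2)), c(1, 1, 1))
#' compute_pdff(f, w)$values[1, 1, 1]  # 25
#' @export
compute_pdff <- function(fat, water) {
  if (!identical(dim(fat$values), dim(water$values))) {
    stop_pdff("fat and water volumes have different shapes.",
              "pdff_alignment_error")
  }
  if (!isTRUE(all.equal(fat$spacing, water$spacing))) {
    stop_pdff("fat and water volumes have different spacings.",
              "pdff_alignment_error")
  }
  if (any(fat$values < 0) || any(water$values < 0)) {
    stop_pdff("signal volumes must be non-negative.", "pdff_domain_error")
  }
  total <- fat$values + water$values
  zero <- total == 0
  total[zero] <- 1  # avoid 0/0; those voxels are forced to 0 below
  pdff <- 100 * fat$values / total
  pdff[zero] <- 0
  out <- volume_grid(pdff, spacing = fat$spacing, origin = fat$origin)
  attr(out, "n_degenerate") <- sum(zero)
  out
}

#' Extract the in-mask voxel sample of a volume
#'
#' @param volume A [volume_grid()].
#' @param mask An [roi_mask()] paired with `volume` and non-empty.
#' @return An `roi_sample`: list with `voxel_values`, `voxel_count`,
#'   `physical_volume` (mm^3 = count x voxel volume), `muscle`, `side`.
#' @export
extract_roi <- function(volume, mask) {
  check_paired(volume, mask)
  keep <- mask$values == 1
  n <- sum(keep)
  if (n == 0L) {
    stop_pdff("mask contains no foreground voxels.", "pdff_empty_roi_error")
  }
  structure(list(voxel_values = as.numeric(volume$values[keep]),
                 voxel_count = n,
                 physical_volume = n * voxel_volume(volume),
                 muscle = mask$muscle, side = mask$side),
            class = "roi_sample")
}
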