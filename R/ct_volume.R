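#' CT volume container
#'
#' A `ct_volume` holds a HU-calibrated 3D scalar grid together with its voxel
#' spacing. Axes are `[x, y, z]` with `z` the axial direction; slice 1 is the
#' most cranial slice. Spacing is in millimetres per voxel along each axis.
#'
#' @param hu_grid 3D numeric array of Hounsfield units.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); `z` is the
#'   axial (slice) spacing.
#' @return An object of class `ct_volume`.
#' @export
as_ct_volume <- function(hu_grid, spacing) {
  if (length(dim(hu_grid)) != 3)
    stop("hu_grid must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (x, y, z) in mm")
  rng <- range(hu_grid)
  if (rng[1] < -1100 || rng[2] > 3000)
    stop("HU values outside the calibrated range [-1100, 3000]")
  structure(list(hu = hu_grid, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$hu), max(x$hu)))
  invisible(x)
}

#' Read and write CT volumes as NIfTI
#'
#' Thin wrappers over RNifti. Voxel spacing is carried in the NIfTI header
#' (`pixdim`). The array axis order on disk matches the in-memory `[x, y, z]`
#' convention with slice 1 most cranial.
#'
#' @param path file path, typically ending in `.nii` or `.nii.gz`.
#' @return `read_ct_nifti` returns a [as_ct_volume()] object.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  as_ct_volume(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[1:3])
}

#' @rdname read_ct_nifti
#' @param volume a `ct_volume`.
#' @export
write_ct_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$hu, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
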