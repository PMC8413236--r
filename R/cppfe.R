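# Computerised PPFE score (cPPFE): the percentage of the upper-zone pleural
# surface occupied by dense tissue.  The pleural surface is represented by
# the most peripheral 3 pixels of the lung cross-section on each axial
# slice; dense tissue is isolated by HU thresholding with small-component
# suppression; the score pools shell voxels over both lungs; a radiologist
# presence gate sets the score to 0% when no PPFE was seen visually.

#' Parameters of the cPPFE quantification
#'
#' @param shell_depth_pixels peripheral band depth in pixels (default 3).
#' @param dense_threshold_hu HU at or above which a shell voxel counts as
#'   dense (default -200; separates fibroelastotic/pleural soft tissue from
#'   aerated lung and is echoed into every result for auditability).
#' @param min_component_shell_voxels in-plane 8-connected dense components
#'   smaller than this are discarded as noise (default 5).
#' @param cutpoint_percent dichotomisation cutpoint on the gated score;
#'   1, 2.5 and 5 are the candidate cutpoints, 2.5 the working default.
#' @param shell_mode `"2d"` (default) erodes each axial cross-section with a
#'   4-connected structuring element; `"3d"` erodes volumetrically
#'   (6-connected).
#' @return A `cppfe_params` list.
#' @export
cppfe_params <- function(shell_depth_pixels = 3L,
                         dense_threshold_hu = -200,
                         min_component_shell_voxels = 5L,
                         cutpoint_percent = 2.5,
                         shell_mode = c("2d", "3d")) {
  shell_mode <- match.arg(shell_mode)
  if (shell_depth_pixels < 1) stop("shell_depth_pixels must be >= 1")
  if (cutpoint_percent <= 0) stop("cutpoint_percent must be > 0")
  structure(list(shell_depth_pixels = as.integer(shell_depth_pixels),
                 dense_threshold_hu = dense_threshold_hu,
                 min_component_shell_voxels =
                   as.integer(min_component_shell_voxels),
                 cutpoint_percent = cutpoint_percent,
                 shell_mode = shell_mode),
            class = "cppfe_params")
}

#' Extract the pleural shell of the upper zone
#'
#' The shell is the lung cross-section minus its `depth`-fold eroded self
#' (4-connected, per axial slice), intersected with the upper zone; where a
#' cross-section is thinner than `depth` the erosion empties it and the whole
#' cross-section is shell.
#'
#' @param mask a [segment_lungs()] lung mask.
#' @param zone an [upper_zone()] object (or a logical array).
#' @param depth shell depth in pixels.
#' @param mode `"2d"` slice-wise (default) or `"3d"` volumetric erosion.
#' @return Logical array: the shell, per lung label preserved via the mask.
#' @export
extract_pleural_shell <- function(mask, zone, depth = 3L,
                                  mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  m <- unclass(mask) > 0L
  zl <- if (inherits(zone, "upper_zone")) zone$zone else zone
  core <- if (mode == "2d") erode_xy4(m, depth) else erode_6(m, depth)
  (m & !core) & zl
}

#' Classify dense voxels within the pleural shell
#'
#' Shell voxels with HU at or above the dense threshold, after removal of
#' in-plane 8-connected components smaller than
#' `params$min_component_shell_voxels`.
#'
#' @param volume a [as_ct_volume()].
#' @param shell logical shell array from [extract_pleural_shell()].
#' @param params a [cppfe_params()].
#' @return Logical array of dense shell voxels.
#' @export
classify_dense_shell <- function(volume, shell, params = cppfe_params()) {
  stopifnot(identical(dim(volume$hu), dim(shell)))
  dense <- shell & volume$hu >= params$dense_threshold_hu
  drop_small_components_xy(dense, params$min_component_shell_voxels)
}

#' Compute the cPPFE score
#'
#' Composes shell extraction and dense classification; the percentage uses
#' shell-voxel counts pooled over both lungs. The returned result is
#' ungated (`vppfe_present = TRUE` equivalent); apply
#' [gate_by_radiologist()] for the analysis score.
#'
#' @param volume a [as_ct_volume()].
#' @param mask a [segment_lungs()] lung mask.
#' @param zone an [upper_zone()] object.
#' @param params a [cppfe_params()].
#' @return A `cppfe_result` list: per-lung and pooled shell/dense counts,
#'   `cppfe_percent`, `gated_percent` (initially equal), `dichotomised`,
#'   and the parameters used.
#' @export
compute_cppfe <- function(volume, mask, zone, params = cppfe_params()) {
  shell <- extract_pleural_shell(mask, zone, params$shell_depth_pixels,
                                 params$shell_mode)
  if (!any(shell)) stop("no pleural surface in zone")
  dense <- classify_dense_shell(volume, shell, params)
  mlab <- unclass(mask)
  per_lung <- lapply(c(right = 1L, left = 2L), function(lv) {
    sm <- shell & mlab == lv
    list(shell_voxels = sum(sm), dense_shell_voxels = sum(dense & sm))
  })
  tot <- sum(shell); dn <- sum(dense)
  pct <- 100 * dn / tot
  structure(list(per_lung = per_lung,
                 shell_voxels_total = tot,
                 dense_shell_voxels_total = dn,
                 cppfe_percent = pct,
                 gated_percent = pct,
                 dichotomised = pct >= params$cutpoint_percent,
                 params = params),
            class = "cppfe_result")
}

#' Apply the radiologist presence gate
#'
#' The computerised score is set to 0% for scans where the radiologist saw
#' no PPFE; otherwise it is passed through unchanged. The dichotomised flag
#' is recomputed on the gated score.
#'
#' @param result a [compute_cppfe()] result.
#' @param vppfe_present logical radiologist presence flag.
#' @return The result with `gated_percent` and `dichotomised` updated.
#' @export
gate_by_radiologist <- function(result, vppfe_present) {
  result$gated_percent <- if (isTRUE(vppfe_present)) result$cppfe_percent else 0
  result$dichotomised <- dichotomise(result$gated_percent,
                                     result$params$cutpoint_percent)
  result
}

#' Dichotomise a gated cPPFE score at a cutpoint
#'
#' Inclusive at the cutpoint: a score exactly at the cutpoint is positive.
#'
#' @param gated_percent gated cPPFE score (percent).
#' @param cutpoint positive cutpoint percent (1, 2.5 or 5 in practice).
#' @return Logical.
#' @export
dichotomise <- function(gated_percent, cutpoint) {
  if (any(cutpoint <= 0)) stop("cutpoint must be > 0")
  gated_percent >= cutpoint
}

#' @export
print.cppfe_result <- function(x, ...) {
  cat(sprintf("<cppfe_result> %.2f%% of %d upper-zone shell voxels dense\n",
              x$cppfe_percent, x$shell_voxels_total))
  cat(sprintf("  gated %.2f%%, %s at cutpoint %.1f%%\n", x$gated_percent,
              if (x$dichotomised) "positive" else "negative",
              x$params$cutpoint_percent))
  invisible(x)
}
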