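# Lung segmentation, carina localisation and upper-zone definition.
#
# The quantification score only needs the lung boundary, the carina slice and
# the HU values, so segmentation is a compact threshold-and-morphology chain:
# air below a HU threshold inside the body, 3D-connected components filtered
# to the two largest (which drops the airway lumen), slice-wise boundary
# restoration, and left/right labelling by centroid.  Dense subpleural
# lesions sit at the lung margin and are *not* enclosed holes, so slice-wise
# hole filling alone cannot return them to the mask; by default each lung
# cross-section is therefore restored to its convex closure, which is exact
# for convex cross-sections and keeps peripheral lesions inside the mask
# (`boundary_fill = "holes"` restricts to plain hole filling).

# Interior (intra-body) air: sub-threshold voxels not connected to the
# lateral faces of the volume.  Only the x/y faces seed the exterior flood:
# the cranial/caudal faces of a chest acquisition cut through the body and
# the airway or lung regularly reaches them.
interior_air <- function(hu, air_threshold_hu) {
  air <- hu < air_threshold_hu
  d <- dim(air)
  lab_air <- label_components_3d(air)
  border_labs <- unique(c(lab_air[1, , ], lab_air[d[1], , ],
                          lab_air[, 1, ], lab_air[, d[2], ]))
  border_labs <- border_labs[border_labs > 0]
  air & !(lab_air %in% border_labs)
}

#' Segment the lungs of a CT volume
#'
#' @param volume a [as_ct_volume()] object containing a body surrounded by
#'   exterior air.
#' @param air_threshold_hu HU threshold separating aerated lung from soft
#'   tissue (default -320).
#' @param min_lung_voxels smallest 3D component accepted as a lung.
#' @param boundary_fill `"smooth"` (default) completes each lung
#'   cross-section boundary with a robust low-order periodic fit of the
#'   boundary radius, reclaiming peripheral defects left where dense
#'   subpleural tissue was excluded by the HU threshold; `"convex"` restores
#'   the convex closure instead; `"holes"` fills enclosed holes only.
#' @return A `lung_mask`: integer array aligned to the volume with 0
#'   background, 1 right lung, 2 left lung.
#' @export
segment_lungs <- function(volume, air_threshold_hu = -320,
                          min_lung_voxels = 500L,
                          boundary_fill = c("smooth", "convex", "holes")) {
  boundary_fill <- match.arg(boundary_fill)
  d <- dim(volume$hu)
  interior <- interior_air(volume$hu, air_threshold_hu)

  lab_int <- label_components_3d(array(interior, d))
  sizes <- tabulate(lab_int[lab_int > 0])
  big <- which(sizes >= min_lung_voxels)
  if (length(big) < 2) stop("lungs not found")
  big <- big[order(sizes[big], decreasing = TRUE)][1:2]

  masks <- lapply(big, function(l) array(lab_int == l, d))
  # left/right assignment by x centroid (x increases towards the patient's
  # left in this convention)
  cx <- vapply(masks, function(m) mean(which(m, arr.ind = TRUE)[, 1]),
               numeric(1))
  right <- masks[[which.min(cx)]]
  left <- masks[[which.max(cx)]]

  out <- array(0L, d)
  for (lv in 1:2) {
    m3 <- if (lv == 1) right else left
    if (boundary_fill == "smooth") {
      m3 <- lung_boundary_restore(m3)
    } else {
      for (k in seq_len(d[3])) {
        if (!any(m3[, , k])) next
        sl <- fill_holes_2d(m3[, , k])
        if (boundary_fill == "convex") sl <- convex_fill_2d(sl)
        m3[, , k] <- sl
      }
    }
    out[m3 & out == 0L] <- lv
  }
  structure(out, class = "lung_mask")
}

#' Locate the carina slice
#'
#' Returns `manual_override` verbatim when supplied (mirroring manual carina
#' identification on clinical reads). Otherwise tracks the cranial airway air
#' column slice-by-slice caudally through the non-lung interior air and
#' returns the first axial slice on which it has split into two in-plane
#' components.
#'
#' @param volume a [as_ct_volume()].
#' @param manual_override optional 1-based slice index, returned verbatim.
#' @param air_threshold_hu HU threshold for airway lumen air.
#' @param lung_mask optional [segment_lungs()] output; computed if missing.
#' @return 1-based axial slice index of the carina.
#' @export
detect_carina <- function(volume, manual_override = NULL,
                          air_threshold_hu = -320, lung_mask = NULL) {
  if (!is.null(manual_override)) return(as.integer(manual_override))
  if (is.null(lung_mask))
    lung_mask <- tryCatch(segment_lungs(volume, air_threshold_hu),
                          error = function(e) NULL)
  d <- dim(volume$hu)
  aw <- interior_air(volume$hu, air_threshold_hu)
  if (!is.null(lung_mask)) aw <- aw & unclass(lung_mask) == 0L

  slice_any <- apply(aw, 3, any)
  if (!any(slice_any)) stop("no airway component found")
  k0 <- which(slice_any)[1]
  prev <- aw[, , k0]
  for (k in (k0 + 1):d[3]) {
    if (k > d[3]) break
    cur <- aw[, , k]
    if (!any(cur)) stop("airway ended before a bifurcation was found")
    lab2 <- label_components_xy(array(cur, c(d[1], d[2], 1L)),
                                connectivity = 8L)[, , 1]
    touching <- unique(lab2[prev & lab2 > 0])
    if (length(touching) >= 2) return(k)
    if (length(touching) == 0)
      stop("airway ended before a bifurcation was found")
    prev <- lab2 == touching
  }
  stop("airway ended before a bifurcation was found")
}

#' Define the upper zone of the lungs
#'
#' The upper zone runs from 5 mm below the lung apex down to (and including)
#' the carina slice. The apex exclusion converts 5 mm to slices with a
#' ceiling so the exclusion never falls short of 5 mm.
#'
#' @param mask a [segment_lungs()] lung mask.
#' @param carina_slice 1-based axial carina slice.
#' @param spacing voxel spacing (x, y, z) in mm, z axial.
#' @param apex_exclusion_mm cranial band excluded from the zone (default 5).
#' @param include_carina_slice logical; the caudal boundary slice is included
#'   by default.
#' @return An `upper_zone` list: `zone` (logical array), `apex_slice`,
#'   `excluded_apex_slices`, `carina_slice`, `zone_slices` (inclusive range).
#' @export
upper_zone <- function(mask, carina_slice, spacing, apex_exclusion_mm = 5,
                       include_carina_slice = TRUE) {
  carina_slice <- as.integer(carina_slice)
  m <- unclass(mask) > 0L
  d <- dim(m)
  slice_any <- apply(m, 3, any)
  if (!any(slice_any)) stop("degenerate upper zone: empty lung mask")
  apex <- which(slice_any)[1]
  excl <- as.integer(ceiling(apex_exclusion_mm / spacing[3]))
  lo <- apex + excl
  hi <- if (include_carina_slice) carina_slice else carina_slice - 1L
  if (hi < lo) stop("degenerate upper zone")
  zone <- m
  zone[, , seq_len(d[3]) < lo | seq_len(d[3]) > hi] <- FALSE
  structure(list(zone = zone, apex_slice = apex,
                 excluded_apex_slices = excl,
                 carina_slice = as.integer(carina_slice),
                 zone_slices = c(lo, min(hi, d[3]))),
            class = "upper_zone")
}
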