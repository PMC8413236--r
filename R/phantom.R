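# CT lung phantoms with known pleural lesion coverage.
#
# The phantom world is deliberately simple: two ellipsoidal lungs inside a
# soft-tissue body cylinder, a tracheal air column that bifurcates at a known
# slice, and subpleural wedge lesions rendered at soft-tissue attenuation
# within the peripheral shell band of the lung.  The quantification pipeline
# only ever sees the lung boundary and HU values, so this geometry exercises
# every step (segmentation, carina tracking, zone cropping, shell extraction,
# dense-tissue thresholding) while the ground truth stays exactly countable
# on the noise-free label grid.

#' Specify a CT lung phantom
#'
#' Defaults describe a coarse-resolution thorax: an 80 x 80 x 56 voxel grid at
#' 2.2 x 2.2 x 2.5 mm spacing, two ellipsoidal lungs with apices at slice 6,
#' a trachea bifurcating at slice 24, aerated lung at -850 HU, body and
#' lesion tissue at +40 HU, exterior air at -1000 HU, and additive Gaussian
#' HU noise (sd 20).
#'
#' @param grid_shape integer length-3, voxels per axis (x, y, z-axial).
#' @param voxel_spacing numeric length-3, mm per voxel.
#' @param lung_centres_xy list with `right` and `left` numeric length-2 voxel
#'   coordinates of each lung's vertical axis.
#' @param lung_centre_z,lung_semiaxes_mm vertical centre (voxel slice) and
#'   ellipsoid semi-axes in mm (x, y, z), shared by both lungs.
#' @param trachea_centre_xy,trachea_radius_mm tracheal air column geometry.
#' @param bifurcation_slice first axial slice (1-based) on which the airway
#'   has split into two bronchi; must be caudal to the lung apex.
#' @param bronchus_offset_mm,bronchus_radius_mm,bronchus_length_slices
#'   geometry of the two child bronchi rendered from the bifurcation slice.
#' @param body_semiaxes_vox semi-axes (voxels) of the elliptical body column.
#' @param hu_values named list: `lung_air`, `soft_tissue`, `ppfe`,
#'   `exterior_air` (HU).
#' @param wedge_list list of wedges, each a list with `side` ("right"/"left"),
#'   `slices` (inclusive 1-based axial range), `theta` (angular sector in
#'   radians, `c(from, to)` anticlockwise, wrapping allowed), and `depth`
#'   (radial extent in voxels from the lung boundary).
#' @param shell_depth_voxels depth (voxels) of the peripheral shell band used
#'   both to confine wedges and to count ground-truth coverage.
#' @param noise_sd additive HU noise standard deviation (>= 0).
#' @param seed integer seed controlling the noise draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(80L, 80L, 56L),
                         voxel_spacing = c(2.2, 2.2, 2.5),
                         lung_centres_xy = list(right = c(22, 42),
                                                left  = c(59, 42)),
                         lung_centre_z = 38,
                         lung_semiaxes_mm = c(26, 34, 80),
                         trachea_centre_xy = c(40.5, 30),
                         trachea_radius_mm = 5.5,
                         bifurcation_slice = 24L,
                         bronchus_offset_mm = 6.6,
                         bronchus_radius_mm = 4,
                         bronchus_length_slices = 5L,
                         body_semiaxes_vox = c(38, 36),
                         hu_values = list(lung_air = -850, soft_tissue = 40,
                                          ppfe = 40, exterior_air = -1000),
                         wedge_list = list(),
                         shell_depth_voxels = 3L,
                         noise_sd = 20,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               lung_centres_xy = lung_centres_xy,
               lung_centre_z = lung_centre_z,
               lung_semiaxes_mm = as.numeric(lung_semiaxes_mm),
               trachea_centre_xy = as.numeric(trachea_centre_xy),
               trachea_radius_mm = trachea_radius_mm,
               bifurcation_slice = as.integer(bifurcation_slice),
               bronchus_offset_mm = bronchus_offset_mm,
               bronchus_radius_mm = bronchus_radius_mm,
               bronchus_length_slices = as.integer(bronchus_length_slices),
               body_semiaxes_vox = as.numeric(body_semiaxes_vox),
               hu_values = hu_values,
               wedge_list = wedge_list,
               shell_depth_voxels = as.integer(shell_depth_voxels),
               noise_sd = noise_sd,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape <= 0))
    stop("grid_shape must be three positive integers")
  if (any(spec$voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$shell_depth_voxels < 1) stop("shell_depth_voxels must be >= 1")
  apex <- phantom_apex_slice(spec)
  if (spec$bifurcation_slice <= apex)
    stop("bifurcation slice must be strictly caudal to the lung apex")
  ext <- phantom_lung_slice_range(spec)
  for (i in seq_along(spec$wedge_list)) {
    w <- spec$wedge_list[[i]]
    if (!w$side %in% c("right", "left"))
      stop(sprintf("wedge %d: side must be 'right' or 'left'", i))
    if (w$slices[1] < ext[1] || w$slices[2] > ext[2] ||
        w$slices[1] > w$slices[2])
      stop(sprintf(
        "wedge %d (%s lung, slices %d-%d) lies outside the lung slice range %d-%d",
        i, w$side, w$slices[1], w$slices[2], ext[1], ext[2]))
    if (is.null(w$depth) || w$depth < 1)
      stop(sprintf("wedge %d: depth must be >= 1 voxel", i))
  }
  invisible(spec)
}

# Most cranial slice containing lung tissue, from the analytic geometry.
phantom_apex_slice <- function(spec) {
  dz <- spec$voxel_spacing[3]
  cz <- spec$lung_centre_z
  az_vox <- spec$lung_semiaxes_mm[3] / dz
  max(1L, as.integer(ceiling(cz - az_vox)))
}

phantom_lung_slice_range <- function(spec) {
  dz <- spec$voxel_spacing[3]
  az_vox <- spec$lung_semiaxes_mm[3] / dz
  c(phantom_apex_slice(spec),
    min(spec$grid_shape[3], as.integer(floor(spec$lung_centre_z + az_vox))))
}

# Noise-free label grid: 0 exterior air, 1 body soft tissue, 2 right lung,
# 3 left lung, 4 airway lumen, 5 lesion in right lung, 6 lesion in left lung.
build_phantom_labels <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$voxel_spacing
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  lab <- array(0L, d)

  # body column
  bx <- (x - (d[1] + 1) / 2) / spec$body_semiaxes_vox[1]
  by <- (y - (d[2] + 1) / 2) / spec$body_semiaxes_vox[2]
  body2d <- outer(bx^2, by^2, `+`) <= 1
  lab[rep(body2d, d[3])] <- 1L

  # lungs: ellipsoids, evaluated in mm
  ax <- spec$lung_semiaxes_mm
  for (side in c("right", "left")) {
    ctr <- spec$lung_centres_xy[[side]]
    ex <- ((x - ctr[1]) * sp[1] / ax[1])^2
    ey <- ((y - ctr[2]) * sp[2] / ax[2])^2
    ez <- ((z - spec$lung_centre_z) * sp[3] / ax[3])^2
    inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
    lab[inside] <- if (side == "right") 2L else 3L
  }

  # airway: trachea column down to the slice before bifurcation, then two
  # bronchi for a few slices
  tc <- spec$trachea_centre_xy
  tr2d <- outer(((x - tc[1]) * sp[1])^2, ((y - tc[2]) * sp[2])^2, `+`) <=
    spec$trachea_radius_mm^2
  for (k in seq_len(min(spec$bifurcation_slice - 1L, d[3])))
    lab[, , k][tr2d] <- 4L
  br_end <- min(d[3], spec$bifurcation_slice + spec$bronchus_length_slices - 1L)
  for (s in c(-1, 1)) {
    bc <- c(tc[1] + s * spec$bronchus_offset_mm / sp[1], tc[2])
    br2d <- outer(((x - bc[1]) * sp[1])^2, ((y - bc[2]) * sp[2])^2, `+`) <=
      spec$bronchus_radius_mm^2
    for (k in spec$bifurcation_slice:br_end)
      lab[, , k][br2d] <- 4L
  }

  # wedges: confined to the peripheral band (lung minus `depth`-fold
  # 4-connected in-plane erosion), within the angular sector
  for (w in spec$wedge_list) {
    side_lab <- if (w$side == "right") 2L else 3L
    lesion_lab <- side_lab + 3L
    ctr <- spec$lung_centres_xy[[w$side]]
    lungm <- lab == side_lab | lab == lesion_lab
    band <- lungm & !erode_xy4(lungm, w$depth)
    theta <- atan2(outer(rep(1, d[1]), y - ctr[2]),
                   outer(x - ctr[1], rep(1, d[2])))
    insec <- in_sector(theta, w$theta)
    sel <- band
    sel[, , seq_len(d[3]) < w$slices[1] | seq_len(d[3]) > w$slices[2]] <- FALSE
    sel <- sel & rep(insec, d[3])
    lab[sel] <- lesion_lab
  }
  lab
}

in_sector <- function(theta, sector) {
  a <- sector[1]; b <- sector[2]
  if (a <= b) theta >= a & theta <= b else theta >= a | theta <= b
}

# Ground-truth shell/zone bookkeeping on the label grid, mirroring the
# quantifier's definitions (apex exclusion by ceiling(5 mm / axial spacing),
# zone down to and including the bifurcation slice).
phantom_ground_truth <- function(spec, lab) {
  d <- spec$grid_shape
  apex <- phantom_apex_slice(spec)
  excl <- as.integer(ceiling(5 / spec$voxel_spacing[3]))
  zone_lo <- apex + excl
  zone_hi <- spec$bifurcation_slice
  zvec <- seq_len(d[3]) >= zone_lo & seq_len(d[3]) <= zone_hi
  out <- list(per_lung = list(), zone_slices = c(zone_lo, zone_hi),
              apex_slice = apex, excluded_apex_slices = excl,
              bifurcation_slice = spec$bifurcation_slice)
  tot_dense <- 0L; tot_shell <- 0L
  for (side in c("right", "left")) {
    side_lab <- if (side == "right") 2L else 3L
    lungm <- lab == side_lab | lab == side_lab + 3L
    shell <- lungm & !erode_xy4(lungm, spec$shell_depth_voxels)
    shell[, , !zvec] <- FALSE
    dense <- shell & lab == side_lab + 3L
    ns <- sum(shell); nd <- sum(dense)
    out$per_lung[[side]] <- list(shell_voxels = ns, dense_shell_voxels = nd)
    tot_shell <- tot_shell + ns; tot_dense <- tot_dense + nd
  }
  out$shell_voxels_total <- tot_shell
  out$dense_shell_voxels_total <- tot_dense
  out$true_cppfe_percent <- if (tot_shell > 0) 100 * tot_dense / tot_shell else 0
  out
}

#' Generate a CT phantom with known pleural lesion coverage
#'
#' Renders the phantom described by a [phantom_spec()] into a HU volume and
#' computes the ground-truth pleural coverage by exact voxel counting on the
#' noise-free label grid. The same seed always yields a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [as_ct_volume()]), `truth` (shell/dense
#'   voxel counts per lung, pooled counts, `true_cppfe_percent`, and the zone
#'   bookkeeping), and `labels` (the noise-free label grid; 0 exterior,
#'   1 body, 2/3 right/left lung, 4 airway, 5/6 lesion right/left).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lab <- build_phantom_labels(spec)
  hu_of <- c(spec$hu_values$exterior_air, spec$hu_values$soft_tissue,
             spec$hu_values$lung_air, spec$hu_values$lung_air,
             spec$hu_values$exterior_air, spec$hu_values$ppfe,
             spec$hu_values$ppfe)
  hu <- array(hu_of[lab + 1L], dim(lab))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd)
  }
  hu <- pmin(pmax(hu, -1090), 2990)
  list(volume = as_ct_volume(hu, spec$voxel_spacing),
       truth = phantom_ground_truth(spec, lab),
       labels = lab)
}

#' Construct wedges covering a requested fraction of the upper-zone shell
#'
#' Builds, independently for each lung, a set of wedges that together cover
#' the requested fraction of the upper-zone pleural shell. The zone is split
#' into blocks of a few axial slices and each block receives one wedge whose
#' angular window is read off the empirical angular distribution of that
#' block's shell voxels (so the counted ground truth lands within a
#' voxel-quantisation error of the request), with the window start rotating
#' from block to block. This mirrors the multifocal, patchy axial
#' distribution of pleurally-based opacities rather than a single
#' full-height plaque.
#'
#' @param spec a [phantom_spec()] (its `wedge_list` is ignored).
#' @param coverage_percent requested pooled coverage, 0-100.
#' @param start_angle named numeric, first-block sector start (radians) per
#'   lung; subsequent blocks rotate by `rotate_by`.
#' @param block_slices axial extent of each wedge, in slices.
#' @param rotate_by radians by which successive blocks' windows rotate.
#' @return The spec with `wedge_list` replaced accordingly.
#' @export
phantom_with_coverage <- function(spec, coverage_percent,
                                  start_angle = c(right = -2.4, left = 0.9),
                                  block_slices = 5L, rotate_by = 2.4) {
  stopifnot(coverage_percent >= 0, coverage_percent <= 100)
  if (coverage_percent == 0) {
    spec$wedge_list <- list()
    return(validate_phantom_spec(spec))
  }
  base <- spec; base$wedge_list <- list()
  lab <- build_phantom_labels(base)
  d <- spec$grid_shape
  apex <- phantom_apex_slice(spec)
  excl <- as.integer(ceiling(5 / spec$voxel_spacing[3]))
  zone <- c(apex + excl, spec$bifurcation_slice)
  blocks <- split(zone[1]:zone[2],
                  (seq_len(zone[2] - zone[1] + 1) - 1) %/% block_slices)
  # low coverage is concentrated into few discrete lesions rather than
  # spread as slivers over every block (a patient with 2% coverage has one
  # small plaque, not eight hairline arcs)
  n_use <- max(1L, min(length(blocks), ceiling(coverage_percent / 6)))
  wedges <- list()
  for (side in c("right", "left")) {
    side_lab <- if (side == "right") 2L else 3L
    lungm <- lab == side_lab
    shell <- lungm & !erode_xy4(lungm, spec$shell_depth_voxels)
    ctr <- spec$lung_centres_xy[[side]]
    zone_n <- sum(shell[, , zone[1]:zone[2]])
    used <- seq_len(n_use)
    used_n <- sum(vapply(blocks[used], function(zb)
      sum(shell[, , zb]), numeric(1)))
    f_local <- min(0.85, coverage_percent / 100 * zone_n / used_n)
    for (b in used) {
      zb <- blocks[[b]]
      sb <- shell
      sb[, , !(seq_len(d[3]) %in% zb)] <- FALSE
      idx <- which(sb, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      th <- atan2(idx[, 2] - ctr[2], idx[, 1] - ctr[1])
      a0 <- start_angle[[side]] + (b - 1) * rotate_by
      rot <- (th - a0) %% (2 * pi)
      m <- round(f_local * length(rot))
      if (m < 1) next
      width <- sort(rot)[m]
      wedges[[length(wedges) + 1]] <-
        list(side = side, slices = range(zb),
             theta = c(wrap_angle(a0), wrap_angle(a0 + width)),
             depth = spec$shell_depth_voxels)
    }
  }
  spec$wedge_list <- wedges
  validate_phantom_spec(spec)
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a
}
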