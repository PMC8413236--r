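# Shared fixtures: a reduced-size phantom for unit tests (same physical
# geometry class as the default, coarser grid for speed) and an independent
# city-block distance transform used as the shell oracle.

small_phantom_spec <- function(..., seed = 1L) {
  args <- list(grid_shape = c(64L, 64L, 44L),
               voxel_spacing = c(2.5, 2.5, 2.5),
               lung_centres_xy = list(right = c(17, 34), left = c(47, 34)),
               lung_centre_z = 34,
               lung_semiaxes_mm = c(26, 34, 75),
               trachea_centre_xy = c(32, 22),
               bifurcation_slice = 20L,
               body_semiaxes_vox = c(30, 29),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# Two-pass city-block (L1) distance to the background, per 2D slice.
# Independent of the package's erosion-based shell: a voxel belongs to the
# depth-d shell iff its L1 distance to the complement is <= d.
l1_distance_to_background_2d <- function(mask) {
  d <- dim(mask)
  INF <- sum(d) + 10
  dist <- matrix(ifelse(mask, INF, 0), d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (dist[i, j] > 0) {
      up <- if (i > 1) dist[i - 1, j] + 1 else INF
      lf <- if (j > 1) dist[i, j - 1] + 1 else INF
      # distance 1 at the image border: outside the grid is background
      edge <- if (i == 1 || j == 1) 1 else INF
      dist[i, j] <- min(dist[i, j], up, lf, edge)
    }
  }
  for (i in rev(seq_len(d[1]))) for (j in rev(seq_len(d[2]))) {
    if (dist[i, j] > 0) {
      dn <- if (i < d[1]) dist[i + 1, j] + 1 else INF
      rt <- if (j < d[2]) dist[i, j + 1] + 1 else INF
      edge <- if (i == d[1] || j == d[2]) 1 else INF
      dist[i, j] <- min(dist[i, j], dn, rt, edge)
    }
  }
  dist
}

# Brute-force ground-truth recount on a phantom label grid: shell voxels
# (per lung, upper zone) and the dense subset, via the L1 distance oracle.
recount_phantom_truth <- function(spec, labels) {
  d <- dim(labels)
  apex <- min(which(apply(labels, 3, function(s)
    any(s %in% c(2L, 3L, 5L, 6L)))))
  excl <- ceiling(5 / spec$voxel_spacing[3])
  zone <- seq(apex + excl, spec$bifurcation_slice)
  shell_n <- 0L; dense_n <- 0L
  for (k in zone) {
    for (side_lab in c(2L, 3L)) {
      lung2d <- labels[, , k] == side_lab | labels[, , k] == side_lab + 3L
      if (!any(lung2d)) next
      dist <- l1_distance_to_background_2d(lung2d)
      shell <- lung2d & dist <= spec$shell_depth_voxels
      shell_n <- shell_n + sum(shell)
      dense_n <- dense_n + sum(shell & labels[, , k] == side_lab + 3L)
    }
  }
  list(shell = shell_n, dense = dense_n,
       percent = if (shell_n > 0) 100 * dense_n / shell_n else 0)
}

# Survival records realising given confusion counts at a 2-year horizon:
# deaths at 1 year, survivors followed to 3 years, censored cut at 1.5.
records_from_counts <- function(tp, fp, fn, tn, censored = 0,
                                censored_flag = TRUE) {
  data.frame(
    id = sprintf("r%03d", seq_len(tp + fp + fn + tn + censored)),
    flag = c(rep(TRUE, tp), rep(TRUE, fp), rep(FALSE, fn), rep(FALSE, tn),
             rep(censored_flag, censored)),
    time = c(rep(1, tp), rep(3, fp), rep(1, fn), rep(3, tn),
             rep(1.5, censored)),
    event = c(rep(1L, tp), rep(0L, fp), rep(1L, fn), rep(0L, tn),
              rep(0L, censored)))
}

# Subjects with identical exact linear trajectories: the interpolation
# limit where the mixed model must reproduce the line.
linear_fvc_data <- function(n = 12, base = 3.0, slope = -0.3,
                            times = c(0, 0.25, 0.5, 0.75, 1, 1.5)) {
  ids <- sprintf("L%02d", seq_len(n))
  fvc_long <- data.frame(id = rep(ids, each = length(times)),
                         time = rep(times, n))
  fvc_long$fvc <- base + slope * fvc_long$time
  set.seed(99)
  subjects <- data.frame(id = ids, age = sample(50:80, n, TRUE),
                         male = rbinom(n, 1, 0.5),
                         smoker = rbinom(n, 1, 0.5),
                         antifibrotic = rbinom(n, 1, 0.5),
                         dlco_ppred = runif(n, 30, 70),
                         baseline_fvc_ppred = runif(n, 50, 100))
  list(fvc_long = fvc_long, subjects = subjects)
}

# Quantify a phantom end to end (segmentation -> carina -> zone -> score).
quantify_phantom <- function(ph, params = cppfe_params()) {
  mask <- segment_lungs(ph$volume)
  car <- detect_carina(ph$volume, lung_mask = mask)
  uz <- upper_zone(mask, car, ph$volume$spacing)
  compute_cppfe(ph$volume, mask, uz, params)
}
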