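make_zone <- function(arr) {
  structure(list(zone = arr, apex_slice = 1L, excluded_apex_slices = 0L,
                 carina_slice = dim(arr)[3], zone_slices = c(1L, dim(arr)[3])),
            class = "upper_zone")
}

test_that("shell of a solid disk matches the distance-transform oracle", {
  d <- c(31, 31, 1)
  m <- array(0L, d)
  cx <- 16; cy <- 16
  for (i in 1:31) for (j in 1:31)
    if ((i - cx)^2 + (j - cy)^2 <= 100) m[i, j, 1] <- 1L
  mask <- structure(m, class = "lung_mask")
  zone <- make_zone(array(TRUE, d))
  shell <- extract_pleural_shell(mask, zone, depth = 3L)
  dist <- l1_distance_to_background_2d(m[, , 1] > 0)
  oracle <- m[, , 1] > 0 & dist <= 3
  expect_identical(shell[, , 1], oracle)
})

test_that("cross-sections thinner than the depth become all shell", {
  d <- c(20, 20, 1)
  m <- array(0L, d)
  m[5:15, 9:11, 1] <- 1L  # 3 voxels thick
  mask <- structure(m, class = "lung_mask")
  shell <- extract_pleural_shell(mask, make_zone(array(TRUE, d)), depth = 3L)
  expect_identical(shell, m > 0)
})

test_that("an empty mask yields an empty shell, and scoring it errors", {
  d <- c(10, 10, 4)
  mask <- structure(array(0L, d), class = "lung_mask")
  zone <- make_zone(array(TRUE, d))
  expect_false(any(extract_pleural_shell(mask, zone, 3L)))
  vol <- as_ct_volume(array(-850, d), c(1, 1, 1))
  expect_error(compute_cppfe(vol, mask, zone), "no pleural surface")
})

test_that("dense classification thresholds and denoises the shell", {
  d <- c(40, 40, 1)
  m <- array(0L, d)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 144) m[i, j, 1] <- 1L
  mask <- structure(m, class = "lung_mask")
  zone <- make_zone(array(TRUE, d))
  shell <- extract_pleural_shell(mask, zone, 3L)

  hu <- array(-850, d)
  vol_air <- as_ct_volume(hu, c(1, 1, 1))
  expect_false(any(classify_dense_shell(vol_air, shell, cppfe_params())))

  # a contiguous dense arc plus two isolated noise spikes
  idx <- which(shell[, , 1], arr.ind = TRUE)
  ang <- atan2(idx[, 2] - 20, idx[, 1] - 20)
  arc <- idx[ang > 0 & ang < 1, , drop = FALSE]
  hu2 <- array(-850, d)
  hu2[cbind(arc, 1)] <- 40
  spikes <- idx[which(ang < -2)[1:2], , drop = FALSE]
  hu2[cbind(spikes, 1)] <- 40
  vol2 <- as_ct_volume(hu2, c(1, 1, 1))
  dense <- classify_dense_shell(vol2, shell,
                                cppfe_params(min_component_shell_voxels = 5L))
  got <- which(dense[, , 1], arr.ind = TRUE)
  expect_identical(got[order(got[, 1], got[, 2]), ],
                   arc[order(arc[, 1], arc[, 2]), ])

  # lowering the threshold never shrinks the dense set (raw thresholding)
  p_hi <- cppfe_params(dense_threshold_hu = -200,
                       min_component_shell_voxels = 1L)
  p_lo <- cppfe_params(dense_threshold_hu = -500,
                       min_component_shell_voxels = 1L)
  d_hi <- classify_dense_shell(vol2, shell, p_hi)
  d_lo <- classify_dense_shell(vol2, shell, p_lo)
  expect_true(all(d_lo[d_hi]))
})

test_that("phantom scoring recovers known coverage and nests its masks", {
  spec <- phantom_with_coverage(small_phantom_spec(seed = 11), 30)
  ph <- generate_phantom(spec)
  mask <- segment_lungs(ph$volume)
  car <- detect_carina(ph$volume, lung_mask = mask)
  uz <- upper_zone(mask, car, ph$volume$spacing)
  res <- compute_cppfe(ph$volume, mask, uz)
  expect_lt(abs(res$cppfe_percent - ph$truth$true_cppfe_percent), 2)

  shell <- extract_pleural_shell(mask, uz, 3L)
  dense <- classify_dense_shell(ph$volume, shell)
  expect_true(all(shell[dense]))
  expect_true(all(uz$zone[shell]))
  expect_true(all((unclass(mask) > 0)[uz$zone]))
})

test_that("zero-wedge phantoms score zero", {
  ph <- generate_phantom(small_phantom_spec(seed = 12))
  res <- quantify_phantom(ph)
  expect_equal(res$cppfe_percent, 0)
})

test_that("the score is invariant to relabelling left and right lungs", {
  spec <- phantom_with_coverage(small_phantom_spec(seed = 13), 18)
  ph <- generate_phantom(spec)
  mask <- segment_lungs(ph$volume)
  car <- detect_carina(ph$volume, lung_mask = mask)
  uz <- upper_zone(mask, car, ph$volume$spacing)
  res <- compute_cppfe(ph$volume, mask, uz)
  m2 <- unclass(mask)
  m2[] <- c(0L, 2L, 1L)[m2 + 1L]
  res2 <- compute_cppfe(ph$volume, structure(m2, class = "lung_mask"), uz)
  expect_equal(res2$cppfe_percent, res$cppfe_percent)
  expect_identical(res2$per_lung$right, res$per_lung$left)
})

test_that("enlarging a wedge sector never decreases the score", {
  base <- small_phantom_spec(seed = 14)
  widths <- c(0.4, 0.9, 1.6, 2.4)
  scores <- vapply(widths, function(w) {
    sp <- base
    sp$wedge_list <- list(list(side = "right", slices = c(8L, 12L),
                               theta = c(-2.4, -2.4 + w), depth = 3L))
    quantify_phantom(generate_phantom(sp))$cppfe_percent
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("score is stable under voxel resolution refinement", {
  lo <- phantom_with_coverage(small_phantom_spec(seed = 15), 20)
  hi <- lo
  hi$grid_shape <- c(96L, 96L, 66L)
  hi$voxel_spacing <- c(5 / 3, 5 / 3, 5 / 3)
  hi$lung_centres_xy <- list(right = c(25.5, 51), left = c(70.5, 51))
  hi$lung_centre_z <- 51
  hi$trachea_centre_xy <- c(48, 33)
  hi$bifurcation_slice <- 30L
  hi$body_semiaxes_vox <- c(45, 43.5)
  hi <- phantom_with_coverage(hi, 20)
  s_lo <- quantify_phantom(generate_phantom(lo))$cppfe_percent
  s_hi <- quantify_phantom(generate_phantom(hi))$cppfe_percent
  expect_lt(abs(s_lo - s_hi), 1)
})

test_that("radiologist gating and dichotomisation behave as specified", {
  spec <- phantom_with_coverage(small_phantom_spec(seed = 16), 4)
  res <- quantify_phantom(generate_phantom(spec))
  gated_neg <- gate_by_radiologist(res, FALSE)
  expect_equal(gated_neg$gated_percent, 0)
  expect_false(gated_neg$dichotomised)
  gated_pos <- gate_by_radiologist(res, TRUE)
  expect_equal(gated_pos$gated_percent, res$cppfe_percent)

  expect_true(dichotomise(2.7, 2.5))
  expect_true(dichotomise(2.5, 2.5))   # inclusive at the cutpoint
  expect_false(dichotomise(0, 1))
  expect_false(dichotomise(0, 5))
  expect_error(dichotomise(1, 0), "cutpoint")
})
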