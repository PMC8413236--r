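# Binary morphology on axial CT grids, implemented as vectorised array
# shifts.  The shell-extraction chain needs exactly 4-connected in-plane
# erosion and 8-connected in-plane component labelling; keeping these
# primitives in-package pins the connectivity conventions down.

# Shift a logical 3D array in-plane (di rows/x, dj cols/y), FALSE fill.
# Slices (3rd axis) are never mixed, so per-slice operations can run on the
# whole volume at once.
shift_xy <- function(m, di, dj) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xs_to <- xs[xs + di >= 1 & xs + di <= d[1]]
  ys_to <- ys[ys + dj >= 1 & ys + dj <= d[2]]
  out[xs_to + di, ys_to + dj, ] <- m[xs_to, ys_to, , drop = FALSE]
  out
}

shift_z <- function(m, dk) {
  d <- dim(m)
  out <- array(FALSE, d)
  zs <- seq_len(d[3])
  zs_to <- zs[zs + dk >= 1 & zs + dk <= d[3]]
  out[, , zs_to + dk] <- m[, , zs_to, drop = FALSE]
  out
}

# 4-connected in-plane erosion/dilation, applied slice-wise to the volume.
erode_xy4 <- function(m, iterations = 1L) {
  for (i in seq_len(iterations)) {
    m <- m &
      shift_xy(m, 1L, 0L) & shift_xy(m, -1L, 0L) &
      shift_xy(m, 0L, 1L) & shift_xy(m, 0L, -1L)
  }
  m
}

dilate_xy4 <- function(m, iterations = 1L) {
  for (i in seq_len(iterations)) {
    m <- m |
      shift_xy(m, 1L, 0L) | shift_xy(m, -1L, 0L) |
      shift_xy(m, 0L, 1L) | shift_xy(m, 0L, -1L)
  }
  m
}

# 3D 6-connected erosion (behind the `mode = "3d"` shell flag).
erode_6 <- function(m, iterations = 1L) {
  for (i in seq_len(iterations)) {
    m <- m &
      shift_xy(m, 1L, 0L) & shift_xy(m, -1L, 0L) &
      shift_xy(m, 0L, 1L) & shift_xy(m, 0L, -1L) &
      shift_z(m, 1L) & shift_z(m, -1L)
  }
  m
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  } else if (connectivity == 8L) {
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
         c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

# Connected-component labelling over the foreground voxel adjacency graph.
# `label_components_xy` labels each axial slice independently (no z edges,
# so labels are unique across the volume); `label_components_3d` adds +/-z.
label_components_graph <- function(m, offsets) {
  d <- dim(m)
  idx <- which(m)
  lab <- array(0L, d)
  if (length(idx) == 0) return(lab)
  pos <- integer(length(m))
  pos[idx] <- seq_along(idx)
  ci <- (idx - 1L) %% d[1] + 1L
  cj <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  ck <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offsets) {
    ni <- ci + o[1]; nj <- cj + o[2]; nk <- ck + o[3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nidx <- (nk[ok] - 1L) * d[1] * d[2] + (nj[ok] - 1L) * d[1] + ni[ok]
    hit <- pos[nidx] > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, pos[nidx][hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# Undirected graph: one offset per neighbour pair suffices.
half_offsets_xy <- function(connectivity) {
  if (connectivity == 4L) list(c(1L, 0L, 0L), c(0L, 1L, 0L))
  else list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(1L, -1L, 0L))
}

label_components_xy <- function(m, connectivity = 8L) {
  label_components_graph(m, half_offsets_xy(connectivity))
}

label_components_3d <- function(m, connectivity = 6L) {
  inplane <- if (connectivity >= 18L) 8L else 4L
  label_components_graph(m, c(half_offsets_xy(inplane),
                              list(c(0L, 0L, 1L))))
}

# Remove in-plane 8-connected components smaller than `min_voxels`
# (slice-wise, the denoising step of the dense-shell classifier).
drop_small_components_xy <- function(m, min_voxels) {
  if (min_voxels <= 1L || !any(m)) return(m)
  lab <- label_components_xy(m, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep & m, dim(m))
}

# Fill a 2D binary cross-section to its convex closure.  The convex hull of
# the foreground pixel centres is intersected with the lattice by half-plane
# tests over the hull edges.
convex_fill_2d <- function(slice) {
  idx <- which(slice, arr.ind = TRUE)
  if (nrow(idx) < 3) return(slice)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  hx <- idx[h, 1]; hy <- idx[h, 2]
  nh <- length(h)
  if (nh < 3) return(slice)
  d <- dim(slice)
  xr <- range(hx); yr <- range(hy)
  gx <- rep(xr[1]:xr[2], times = yr[2] - yr[1] + 1)
  gy <- rep(yr[1]:yr[2], each = xr[2] - xr[1] + 1)
  inside <- rep(TRUE, length(gx))
  # chull returns vertices clockwise; points must lie on the clockwise side
  # (non-positive cross product) of every edge
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == nh) 1 else e + 1]; y2 <- hy[if (e == nh) 1 else e + 1]
    cr <- (x2 - x1) * (gy - y1) - (y2 - y1) * (gx - x1)
    inside <- inside & cr <= 0
  }
  out <- slice
  out[cbind(gx[inside], gy[inside])] <- TRUE
  out
}

# Restore a lung component whose boundary has been bitten into by dense
# subpleural tissue (which HU thresholding excludes from the mask).
#
# A wide shallow peripheral defect is shape-degenerate on a single slice: a
# depth-3 bite spanning a quarter of the circumference of an elliptical
# cross-section is almost indistinguishable, about the damaged centroid,
# from a slightly shifted smaller ellipse.  What does identify it is axial
# coherence: subpleural lesions are confined to a limited slice range while
# the rest of the lung is clean, and neighbouring cross-sections are close
# to scaled copies of one another.  The boundary radius surface is therefore
# modelled separably as
#     r_k(theta) ~ s_k * rho(theta) + a_k cos(theta) + b_k sin(theta)
# (per-slice scale s_k plus recentring terms a_k, b_k; rho a shared angular
# shape), estimated by alternating robust steps: rho from per-bin upper
# quantiles of scale-normalised profiles across slices, per-slice
# coefficients by trimmed least squares excluding bins that fall well short
# of the current surface.  Bins short of the converged surface by more than
# `defect_voxels` are grown back out to it; the mask is never shrunk.
lung_boundary_restore <- function(m, nbins = 90L, defect_voxels = 1.1,
                                  fill_margin = 0.4,
                                  min_slice_pixels = 12L, n_outer = 3L) {
  d <- dim(m)
  npx <- apply(m, 3, sum)
  ks <- which(npx >= min_slice_pixels)
  if (length(ks) < 4) return(m)
  filled <- m
  for (k in ks) filled[, , k] <- fill_holes_2d(m[, , k])

  cent <- t(vapply(ks, function(k) colMeans(which(filled[, , k],
                                                  arr.ind = TRUE)),
                   numeric(2)))
  # robust straightened axis: size-weighted quadratic trend of the centroid
  cxf <- stats::fitted(stats::lm(cent[, 1] ~ stats::poly(ks, 2),
                                 weights = npx[ks]))
  cyf <- stats::fitted(stats::lm(cent[, 2] ~ stats::poly(ks, 2),
                                 weights = npx[ks]))
  R <- vapply(seq_along(ks), function(j)
    ray_radius_profile(filled[, , ks[j]], cxf[j], cyf[j], nbins),
    numeric(nbins))

  th <- (seq_len(nbins) - 0.5) / nbins * 2 * pi - pi
  basis_cs <- cbind(cos(th), sin(th))
  s <- apply(R, 2, stats::quantile, 0.6, na.rm = TRUE)
  ab <- matrix(0, length(ks), 2)
  rho <- apply(sweep(R, 2, s, "/"), 1, stats::quantile, 0.75, na.rm = TRUE)
  for (outer_it in seq_len(n_outer)) {
    Rhat <- outer(rho, s) + basis_cs %*% t(ab)
    for (j in seq_along(ks)) {
      y <- R[, j]
      ok <- !is.na(y) & !is.na(rho)
      for (it in 1:3) {
        keep <- ok & (y - Rhat[, j]) >= -defect_voxels
        if (sum(keep) < 8) break
        Xj <- cbind(rho[keep], basis_cs[keep, , drop = FALSE])
        cf <- stats::lm.fit(Xj, y[keep])$coefficients
        cf[is.na(cf)] <- 0
        s[j] <- cf[1]; ab[j, ] <- cf[2:3]
        Rhat[, j] <- rho * s[j] + drop(basis_cs %*% cf[2:3])
      }
    }
    norm <- sweep(R - basis_cs %*% t(ab), 2, s, "/")
    rho <- apply(norm, 1, stats::quantile, 0.75, na.rm = TRUE)
  }
  Rhat <- outer(rho, s) + basis_cs %*% t(ab)
  defect <- !is.na(R) & (R < Rhat - defect_voxels)

  out <- filled
  for (j in seq_along(ks)) {
    if (!any(defect[, j])) next
    k <- ks[j]
    r_fill <- ifelse(defect[, j],
                     pmax(R[, j], Rhat[, j] + fill_margin), R[, j])
    rmax <- max(r_fill, na.rm = TRUE)
    xr <- max(1, floor(cxf[j] - rmax - 1)):min(d[1], ceiling(cxf[j] + rmax + 1))
    yr <- max(1, floor(cyf[j] - rmax - 1)):min(d[2], ceiling(cyf[j] + rmax + 1))
    gx <- rep(xr, times = length(yr)); gy <- rep(yr, each = length(xr))
    gth <- atan2(gy - cyf[j], gx - cxf[j])
    gr <- sqrt((gx - cxf[j])^2 + (gy - cyf[j])^2)
    gbin <- pmin(nbins, floor((gth + pi) / (2 * pi) * nbins) + 1L)
    inside <- defect[gbin, j] & gr <= r_fill[gbin]
    sl <- out[, , k]
    sl[cbind(gx[inside], gy[inside])] <- TRUE
    out[, , k] <- sl
  }
  out
}

# Boundary radius per angular bin by ray marching from (cx, cy): the largest
# sub-voxel step at which the nearest voxel is foreground.
ray_radius_profile <- function(slice, cx, cy, nbins, step = 0.3) {
  d <- dim(slice)
  th <- (seq_len(nbins) - 0.5) / nbins * 2 * pi - pi
  ts <- seq(1, max(d) / 1.5, by = step)
  gx <- round(outer(cos(th), ts) + cx)
  gy <- round(outer(sin(th), ts) + cy)
  ok <- gx >= 1 & gx <= d[1] & gy >= 1 & gy <= d[2]
  v <- matrix(FALSE, nbins, length(ts))
  v[ok] <- slice[cbind(gx[ok], gy[ok])]
  apply(v, 1, function(row) if (any(row)) ts[max(which(row))] else NA_real_)
}

fourier_basis <- function(theta, harmonics) {
  X <- matrix(1, length(theta), 1 + 2 * harmonics)
  for (h in seq_len(harmonics)) {
    X[, 2 * h] <- cos(h * theta)
    X[, 2 * h + 1] <- sin(h * theta)
  }
  X
}

# Slice-wise hole filling: background 4-connected components not reachable
# from the slice border are holes.
fill_holes_2d <- function(slice) {
  d <- dim(slice)
  bg <- !slice
  reach <- array(FALSE, c(d, 1L))
  b <- array(bg, c(d, 1L))
  reach[1, , 1] <- b[1, , 1]; reach[d[1], , 1] <- b[d[1], , 1]
  reach[, 1, 1] <- b[, 1, 1]; reach[, d[2], 1] <- b[, d[2], 1]
  repeat {
    grown <- (reach | dilate_xy4(reach)) & b
    if (identical(grown, reach)) break
    reach <- grown
  }
  slice | (bg & !reach[, , 1])
}
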