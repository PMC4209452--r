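# Shared fixtures and independent oracles. Oracles deliberately use plain
# double loops / dense algebra so they share no code path with the package
# implementations they check.

FWHM_K <- 2 * sqrt(2 * log(2))

unit_illum <- function(n = 120L) illumination_field(matrix(1, n, n))

toy_cam <- function(...) camera_model(...)

# A small steep phantom whose capillary fits comfortably in a 120 px
# (43 mm) field of view.
toy_phantom <- function(...) {
  args <- utils::modifyList(list(
    gel_radius_mm = 14, gel_length_mm = 40,
    capillary_fill_length_mm = 30, inclination_deg = 30,
    entry_point_mm = c(-14, 0, 1), dye_concentration_uM = 100,
    activity_MBq_per_mL = 5, mu_ex_per_mm = 0.05, mu_em_per_mm = 0.03,
    blur_sigma0_mm = 0.25, blur_growth_per_mm = 0.035,
    background_fraction = 0.05), list(...))
  do.call(phantom_spec, args)
}

# A phantom holding a single near-point source element at (x0, 0, depth).
point_phantom <- function(depth, mu_total = 0.1, x0 = 0, ...) {
  phantom_spec(gel_radius_mm = 14, gel_length_mm = 40,
               capillary_fill_length_mm = 0.05, inclination_deg = 0.001,
               entry_point_mm = c(x0, 0, depth), dye_concentration_uM = 100,
               mu_ex_per_mm = mu_total / 2, mu_em_per_mm = mu_total / 2,
               blur_sigma0_mm = 0, blur_growth_per_mm = 0,
               background_fraction = 0, ...)
}

# Dense 2-D convolution with a separable truncated Gaussian, renormalized
# at the edges -- written as an explicit quadruple loop.
dense_blur2d <- function(m, sigma_px, trunc = 4) {
  r <- max(1L, ceiling(trunc * sigma_px))
  off <- -r:r
  k2 <- outer(exp(-off^2 / (2 * sigma_px^2)),
              exp(-off^2 / (2 * sigma_px^2)))
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0; wsum <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      ii <- i + off[a]; jj <- j + off[b]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        s <- s + k2[a, b] * m[ii, jj]
        wsum <- wsum + k2[a, b]
      }
    }
    out[i, j] <- s / wsum
  }
  out
}

# Dense per-angle projection matrix, independent reimplementation of the
# linear voxel-splat weights.
dense_angle_matrix <- function(phi, ny, nz, voxel_mm, n_u, bin_mm) {
  M <- matrix(0, n_u, ny * nz)
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) {
    y <- (iy - 0.5 - ny / 2) * voxel_mm
    z <- (iz - 0.5 - nz / 2) * voxel_mm
    g <- (y * cos(phi) + z * sin(phi)) / bin_mm + n_u / 2 + 0.5
    k0 <- floor(g); w <- g - k0
    col <- iy + (iz - 1L) * ny
    if (k0 >= 1 && k0 <= n_u) M[k0, col] <- M[k0, col] + (1 - w)
    if (k0 + 1 >= 1 && k0 + 1 <= n_u) M[k0 + 1, col] <- M[k0 + 1, col] + w
  }
  M
}

# Brute-force dense MLEM on a stacked system matrix, slice by slice.
mlem_oracle <- function(counts, geom, vol_dim, n_iter) {
  nx <- vol_dim[1]; ny <- vol_dim[2]; nz <- vol_dim[3]
  A <- do.call(rbind, lapply(geom$angles_rad, dense_angle_matrix,
                             ny = ny, nz = nz, voxel_mm = geom$bin_mm,
                             n_u = geom$n_u, bin_mm = geom$bin_mm))
  sens <- colSums(A)
  mask <- sens > 0
  vol <- array(0, vol_dim)
  for (x in seq_len(nx)) {
    y <- as.vector(t(counts[, , x]))   # u fastest within each angle block
    v <- rep(1, ny * nz)
    for (it in seq_len(n_iter)) {
      fp <- as.vector(A %*% v)
      ratio <- ifelse(fp > 1e-12, y / pmax(fp, 1e-12), 0)
      bp <- as.vector(crossprod(A, ratio))
      v[mask] <- v[mask] * bp[mask] / sens[mask]
    }
    vol[x, , ] <- matrix(v, ny, nz)
  }
  vol
}

# Brute-force FWHM: resample the profile on a dense grid and scan for the
# half-maximum crossings, using the same outer-20% pedestal convention.
brute_fwhm <- function(x, v, dense_n = 20001L) {
  n <- length(x)
  k <- max(1L, round(0.1 * n))
  v <- v - stats::median(c(v[seq_len(k)], v[(n - k + 1L):n]))
  xd <- seq(min(x), max(x), length.out = dense_n)
  vd <- stats::approx(x, v, xd)$y
  imax <- which.max(vd)
  half <- vd[imax] / 2
  li <- which(vd[seq_len(imax)] <= half)
  ri <- which(vd[imax:dense_n] <= half) + imax - 1L
  if (!length(li) || !length(ri)) return(NA_real_)
  xd[ri[1]] - xd[max(li)]
}

# Classed depth-curve builder for direct construction in tests.
make_signal_curve <- function(depth_mm, raw, background_mean,
                              background_sd) {
  sub <- raw - background_mean
  out <- data.frame(depth_mm = depth_mm, value = sub / max(sub))
  attr(out, "value_kind") <- "signal"
  attr(out, "raw") <- raw
  attr(out, "background_mean") <- background_mean
  attr(out, "background_sd") <- background_sd
  class(out) <- c("depth_curve", "data.frame")
  out
}

# Wrap a bare sinogram array so the reconstruction API accepts it.
as_sinogram <- function(counts, geom) {
  structure(list(counts = counts, window = photopeak_window(140),
                 geom = geom, discarded = 0L), class = "sinogram_set")
}

# Elongated-ellipse test scene for registration (value 1 inside).
ellipse_image <- function(n = 128L, ps = 0.36, a = 15, b = 6) {
  x <- (seq_len(n) - 0.5) * ps - n * ps / 2
  m <- outer(x^2 / b^2, x^2 / a^2, "+") <= 1
  image2d(m * 1.0 + 1e-3, ps, 1, "photo")
}
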