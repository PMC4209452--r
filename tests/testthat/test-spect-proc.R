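test_that("photopeak windows follow the fractional-width closed form", {
  w <- photopeak_window(140, 0.20)
  expect_equal(c(w$lo_keV, w$hi_keV), c(126, 154), tolerance = 1e-12)
  w2 <- photopeak_window(171, 0.20)
  expect_equal(c(w2$lo_keV, w2$hi_keV), c(153.9, 188.1), tolerance = 1e-12)
  w3 <- photopeak_window(100, 1e-6)
  expect_lt(w3$width_keV, 1e-3)
  expect_error(photopeak_window(140, 0))
  expect_error(photopeak_window(140, 1.2))
  expect_error(energy_window(130, 120))
})

test_that("event binning partitions and tallies discards exactly", {
  geom <- spect_geometry(8, 16, 16, 1.0)
  w <- photopeak_window(140, 0.2)
  empty <- data.frame(angle_index = integer(0), u_mm = numeric(0),
                      v_mm = numeric(0), energy_keV = numeric(0))
  s0 <- bin_events(empty, w, geom)
  expect_equal(sum(s0$counts), 0)

  one <- data.frame(angle_index = 3L, u_mm = 0.2, v_mm = -0.7,
                    energy_keV = 140)
  s1 <- bin_events(one, w, geom)
  expect_equal(sum(s1$counts), 1)
  expect_equal(s1$counts[4, 9, 8], 1)   # half-open bins around 0

  # partition: disjoint windows cover every event exactly once
  acq <- acquisition_spec(exposure_s = 30, scatter_fraction = 0.3,
                          energy_resolution_fwhm_frac = 0.05,
                          scatter_energy_frac = c(0.5, 1.15))
  ev <- simulate_listmode(toy_phantom(), acq, seed = 9)
  expect_gt(nrow(ev), 1000)
  big <- spect_geometry(32, 80, 80, 1.0)
  wins <- list(photopeak_window(140, 0.2),          # [126, 154)
               energy_window(70, 126), energy_window(154, 176))
  n_in <- vapply(wins, function(wx) {
    s <- bin_events(ev, wx, big)
    sum(s$counts) + s$discarded
  }, numeric(1))
  out_of_window <- sum(ev$energy_keV < 70 | ev$energy_keV >= 176)
  expect_identical(sum(n_in) + out_of_window, as.numeric(nrow(ev)))

  # in-window total = binned + discarded even on a grid that clips events
  tiny <- spect_geometry(32, 6, 6, 1.0)
  st <- bin_events(ev, wins[[1]], big)
  st2 <- bin_events(ev, wins[[1]], tiny)
  expect_gt(st2$discarded, 0)
  expect_equal(sum(st2$counts) + st2$discarded,
               sum(st$counts) + st$discarded)
})

test_that("photopeak window captures the primary fraction", {
  # continuum strictly below the photopeak window: in-window counts are
  # a Binomial(n, 1 - scatter_fraction) draw
  acq <- acquisition_spec(exposure_s = 35, scatter_fraction = 0.3,
                          energy_resolution_fwhm_frac = 0.05,
                          scatter_energy_frac = c(0.45, 0.88),
                          sensitivity_counts_per_MBq_s = 2500)
  sp <- toy_phantom()
  ev <- simulate_listmode(sp, acq, seed = 12)
  n <- nrow(ev)
  expect_gt(n, 8000)
  inw <- sum(ev$energy_keV >= 126 & ev$energy_keV < 154)
  expect_lt(abs(inw - 0.7 * n), 5 * sqrt(n * 0.7 * 0.3))
})

test_that("TEW scatter estimate matches the worked formula and clamps", {
  geom <- spect_geometry(2, 2, 2, 1.0)
  mk <- function(val, lo, hi) {
    structure(list(counts = array(val, c(2, 2, 2)),
                   window = energy_window(lo, hi), geom = geom,
                   discarded = 0L), class = "sinogram_set")
  }
  low <- mk(10, 124, 136)   # width 12 keV
  high <- mk(10, 166, 184)  # width 18 keV
  est <- tew_scatter_estimate(low, high, 28)
  expect_equal(est[1, 1, 1], (10 / 12 + 10 / 18) * 14, tolerance = 1e-12)
  expect_equal(est[1, 1, 1], 19.444, tolerance = 1e-3)
  # zero backgrounds -> zero estimate
  expect_equal(max(tew_scatter_estimate(mk(0, 124, 136), mk(0, 166, 184),
                                        28)), 0)
  # corrected counts never negative
  set.seed(4)
  peak <- mk(2, 126, 154)
  peak$counts <- array(rpois(8, 2), c(2, 2, 2))
  corr <- tew_correct(peak, est)
  expect_true(all(corr$counts >= 0))
})

test_that("projector and back projector are exact adjoints", {
  set.seed(15)
  for (rep in 1:5) {
    ny <- sample(5:9, 1); nz <- sample(5:9, 1); nx <- sample(3:6, 1)
    g <- spect_geometry(sample(4:9, 1), sample(6:12, 1), nx, 0.8)
    vol <- volume3d(array(runif(nx * ny * nz), c(nx, ny, nz)), 0.8)
    y <- array(runif(g$n_angles * g$n_u * g$n_v),
               c(g$n_angles, g$n_u, g$n_v))
    lhs <- sum(forward_project(vol, g) * y)
    rhs <- sum(vol$voxels * back_project(y, g, c(nx, ny, nz))$voxels)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("one-subset OSEM equals dense brute-force MLEM per iterate", {
  set.seed(16)
  g <- spect_geometry(8, 18, 16, 1.0)
  truth <- array(0, c(16, 16, 16))
  truth[8, 6, 10] <- 50; truth[4, 11, 7] <- 30
  sino <- forward_project(volume3d(truth, 1.0), g)
  noisy <- array(rpois(length(sino), sino), dim(sino))
  ss <- as_sinogram(noisy, g)
  for (k in c(1L, 3L)) {
    suppressWarnings(rec <- osem_reconstruct(ss, n_subsets = 1,
                                             n_iterations = k,
                                             vol_dim = c(16, 16, 16)))
    oracle <- mlem_oracle(noisy, g, c(16, 16, 16), k)
    expect_lt(max(abs(rec$voxels - oracle)), 1e-10)
  }
})

test_that("OSEM localizes a noiseless point source and preserves counts", {
  # all-zero sinogram is a fixed point
  g <- spect_geometry(16, 10, 8, 1.0)
  z <- as_sinogram(array(0, c(16, 10, 8)), g)
  suppressWarnings(rec0 <- osem_reconstruct(z, 4, 3, c(8, 8, 8)))
  expect_equal(max(rec0$voxels), 0)

  # point source, 16 subsets x 6 iterations: argmax within one voxel,
  # agreeing with the dense MLEM oracle's argmax
  tr <- array(0, c(8, 8, 8)); tr[5, 3, 6] <- 100
  sino <- forward_project(volume3d(tr, 1.0), g)
  ss <- as_sinogram(sino, g)
  suppressWarnings(rec <- osem_reconstruct(ss, 16, 6, c(8, 8, 8)))
  am <- which(rec$voxels == max(rec$voxels), arr.ind = TRUE)[1, ]
  expect_true(all(abs(am - c(5, 3, 6)) <= 1))
  oam <- mlem_oracle(sino, g, c(8, 8, 8), 20)
  oam <- which(oam == max(oam), arr.ind = TRUE)[1, ]
  expect_true(all(abs(am - oam) <= 1))

  # MLEM count preservation on a 16^3 toy after 50 iterations
  set.seed(17)
  g2 <- spect_geometry(12, 18, 16, 1.0)
  v <- array(runif(16^3), c(16, 16, 16))
  sino2 <- forward_project(volume3d(v, 1.0), g2)
  noisy2 <- array(rpois(length(sino2), sino2 * 5), dim(sino2))
  suppressWarnings(rec2 <- osem_reconstruct(as_sinogram(noisy2, g2), 1, 50,
                                            c(16, 16, 16)))
  reproj <- forward_project(rec2, g2)
  expect_lt(abs(sum(reproj) - sum(noisy2)) / sum(noisy2), 0.005)
})

test_that("Gaussian post-filter has the right width and conserves mass", {
  v <- array(0, c(33, 33, 33)); v[17, 17, 17] <- 1
  vol <- volume3d(v, 0.2)
  f <- gaussian_postfilter(vol, 0.47)
  prof <- structure(list(positions_mm = ((1:33) - 17) * 0.2,
                         values = f$voxels[17, 17, ],
                         averaging_width_mm = 0.2,
                         orientation = "orthogonal", modality = "spect_sum"),
                    class = "line_profile")
  expect_equal(estimate_fwhm(prof), 0.47, tolerance = 0.1 / 0.47)

  cv <- volume3d(array(3.5, c(10, 12, 9)), 0.2)
  fc <- gaussian_postfilter(cv, 1.18)
  expect_lt(max(abs(fc$voxels - 3.5)), 1e-10)

  set.seed(18)
  rv <- volume3d(array(runif(24^3), c(24, 24, 24)), 0.2)
  fr <- gaussian_postfilter(rv, 1.18)
  expect_lt(abs(sum(fr$voxels) - sum(rv$voxels)) / sum(rv$voxels), 1e-3)
})

test_that("sum projections conserve intensity along each axis", {
  v <- volume3d(array(1, c(10, 12, 25)), 0.2)
  top <- sum_projection(v, "vertical")
  expect_equal(dim(top$pixels), c(12L, 10L))   # rows y, cols x
  expect_true(all(top$pixels == 25))
  expect_identical(top$modality, "spect_sum")
  expect_identical(top$pixel_size_mm, 0.2)

  set.seed(19)
  rv <- volume3d(array(runif(10 * 12 * 25), c(10, 12, 25)), 0.2)
  for (ax in c("vertical", "lateral", "axial"))
    expect_equal(sum(sum_projection(rv, ax)$pixels), sum(rv$voxels),
                 tolerance = 1e-12)
  side <- sum_projection(rv, "lateral")
  expect_equal(dim(side$pixels), c(25L, 10L))  # rows z, cols x
})
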