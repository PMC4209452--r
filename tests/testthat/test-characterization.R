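test_that("profile extraction averages over the stated width", {
  # constant image -> constant profile
  img <- image2d(matrix(4.2, 60, 60), 0.5, 1, "photo")
  p <- extract_profile(img, c(-10, 0), c(10, 0), width_mm = 1.5)
  expect_true(all(abs(p$values - 4.2) < 1e-12))
  expect_equal(p$positions_mm, seq(0, 20, by = 0.5))

  # profile along a 1-pixel line of value v, 3 px averaging width: v / 3
  m <- matrix(0, 41, 41); m[21, ] <- 9
  img2 <- image2d(m, 1, 1, "photo")
  p2 <- extract_profile(img2, c(-15, 0), c(15, 0), width_mm = 3)
  expect_true(all(abs(p2$values - 3) < 1e-12))
  expect_equal(p2$averaging_width_mm, 3)

  # segment outside the image errors
  expect_error(extract_profile(img, c(-10, 0), c(100, 0)), "outside")
})

test_that("axial-to-depth mapping is affine, exact, and invertible", {
  expect_equal(axial_to_depth(5, 45), 5, tolerance = 1e-12)
  expect_equal(axial_to_depth(10, 30), 5.773503, tolerance = 1e-6)
  expect_equal(axial_to_depth(3, 25, entry_axial_mm = 3,
                              entry_depth_mm = 1.5), 1.5)
  x <- seq(-10, 25, by = 0.37)
  d <- axial_to_depth(x, 20, 2, 1)
  expect_false(is.unsorted(d))
  x_back <- 2 + (d - 1) / tan(20 * pi / 180)
  expect_equal(x_back, x, tolerance = 1e-12)
  expect_error(axial_to_depth(1, 0))
  expect_error(axial_to_depth(1, 90))
})

test_that("FWHM estimation matches closed forms and a brute-force search", {
  x <- seq(-5, 5, by = 0.05)
  gauss <- structure(list(positions_mm = x, values = exp(-x^2 / 2),
                          averaging_width_mm = 1, orientation = "orthogonal",
                          modality = "fluorescence"),
                     class = "line_profile")
  expect_equal(estimate_fwhm(gauss), 2 * sqrt(2 * log(2)),
               tolerance = 0.02 / 2.3548)

  # rectangular pulse of width 2.0 -> 2.0 within one step
  rect <- gauss; rect$values <- as.numeric(abs(x) < 1)
  expect_lt(abs(estimate_fwhm(rect) - 2), 0.05 + 1e-9)

  # chord profile of a 0.9 mm cylinder: FWHM = 0.9 * sqrt(3) / 2
  xc <- seq(-1.5, 1.5, by = 0.05)
  chord <- gauss
  chord$positions_mm <- xc
  chord$values <- sqrt(pmax(0.9^2 - 4 * xc^2, 0))
  expect_lt(abs(estimate_fwhm(chord) - 0.9 * sqrt(3) / 2), 0.05 + 1e-9)

  # truncated peak errors
  trunc <- gauss; trunc$values <- exp(-(x - 6)^2 / 2)
  expect_error(estimate_fwhm(trunc), "truncated")

  # agreement with dense brute-force search on random unimodal profiles
  set.seed(31)
  for (i in 1:100) {
    step <- runif(1, 0.03, 0.08)
    xs <- seq(-6, 6, by = step)
    sig <- runif(1, 0.4, 2)
    ped <- runif(1, 0, 0.3)
    vs <- ped + runif(1, 0.5, 2) * exp(-(xs - runif(1, -1, 1))^2 /
                                         (2 * sig^2))
    pr <- structure(list(positions_mm = xs, values = vs,
                         averaging_width_mm = 1, orientation = "orthogonal",
                         modality = "fluorescence"),
                    class = "line_profile")
    expect_lt(abs(estimate_fwhm(pr) - brute_fwhm(xs, vs)), step + 1e-9)
  }
})

test_that("attenuation curves recover the forward model", {
  cam <- toy_cam(); il <- unit_illum()
  bg_region <- list(x_mm = c(-15, 5), y_mm = c(6, 12))

  # no attenuation, no blur growth: flat at 1 (noiseless)
  sp0 <- toy_phantom(mu_ex_per_mm = 0, mu_em_per_mm = 0,
                     blur_growth_per_mm = 0, background_fraction = 0)
  img0 <- render_fluorescence(sp0, cam, il, noise = FALSE)
  gt0 <- ground_truth_capillary(sp0)
  cur0 <- attenuation_curve(img0, gt0, bg_region)
  core <- cur0$value[cur0$depth_mm > 2 & cur0$depth_mm <
                       max(cur0$depth_mm) - 2]
  expect_lt(max(abs(core - 1)), 0.02)
  expect_equal(max(cur0$value), 1)

  # known mu_total: curve matches exp(-mu (z - z_min)) with RMS < 3%
  sp1 <- toy_phantom(mu_ex_per_mm = 0.05, mu_em_per_mm = 0.03,
                     blur_growth_per_mm = 0, background_fraction = 0)
  img1 <- render_fluorescence(sp1, cam, il, noise = FALSE)
  gt1 <- ground_truth_capillary(sp1)
  cur1 <- attenuation_curve(img1, gt1, bg_region)
  keep <- cur1$depth_mm > 2 & cur1$depth_mm < max(cur1$depth_mm) - 2
  model <- exp(-0.08 * (cur1$depth_mm[keep] - min(cur1$depth_mm[keep])))
  model <- model / max(model)
  ratio <- max(cur1$value[keep]) # renormalize over the kept range
  expect_lt(sqrt(mean((cur1$value[keep] / ratio - model)^2)), 0.03)

  # background region overlapping the capillary is rejected
  expect_error(attenuation_curve(img1, gt1,
                                 list(x_mm = c(-10, 0), y_mm = c(-1, 1))),
               "overlaps")
})

test_that("resolution curves track the blur model", {
  cam <- toy_cam(); il <- unit_illum()
  sp_flat <- toy_phantom(blur_growth_per_mm = 0, background_fraction = 0)
  img_flat <- render_fluorescence(sp_flat, cam, il, noise = FALSE)
  gt <- ground_truth_capillary(sp_flat)
  depths <- c(3, 6, 9, 12)
  rc_flat <- resolution_curve(img_flat, gt, depths)
  expect_identical(attr(rc_flat, "value_kind"), "fwhm")
  expect_lt(diff(range(rc_flat$value)), cam$pixel_size_mm)

  sp_grow <- toy_phantom(blur_growth_per_mm = 0.05,
                         background_fraction = 0)
  img_grow <- render_fluorescence(sp_grow, cam, il, noise = FALSE)
  rc <- resolution_curve(img_grow, ground_truth_capillary(sp_grow), depths)
  expect_true(all(diff(rc$value) > 0))
  expect_gt(rc$value[length(depths)], rc_flat$value[1])

  # depths outside the capillary span are rejected
  expect_error(resolution_curve(img_grow, gt, c(3, 40)), "outside")
})

test_that("peak-to-background ratio follows the generator algebra", {
  expect_equal(peak_background_ratio(
    structure(list(positions_mm = 1:5, values = c(1, 2, 2.5, 2, 1),
                   averaging_width_mm = 1, orientation = "axial",
                   modality = "fluorescence"), class = "line_profile"),
    1.0), 2.5)
  expect_error(peak_background_ratio(
    structure(list(positions_mm = 1:5, values = rep(1, 5),
                   averaging_width_mm = 1, orientation = "axial",
                   modality = "fluorescence"), class = "line_profile"),
    0), "positive")

  # noiseless simulation with background fraction b and mu = 0:
  # raw peak / background level = (1 + b) / b
  b <- 0.05
  sp <- toy_phantom(mu_ex_per_mm = 0, mu_em_per_mm = 0,
                    blur_growth_per_mm = 0, background_fraction = b)
  img <- render_fluorescence(sp, toy_cam(), unit_illum(), noise = FALSE)
  gt <- ground_truth_capillary(sp)
  # single-pixel width so the profile peak equals the image peak level
  prof <- extract_profile(img, c(min(gt$x_mm), 0), c(max(gt$x_mm), 0),
                          width_mm = 0.3)
  bg_level <- mean(img$pixels[5:15, 50:70])
  expect_equal(peak_background_ratio(prof, bg_level), (1 + b) / b,
               tolerance = 0.05)
})

test_that("detectability depth interpolates the crossing", {
  d <- seq(0, 30, by = 0.5)
  # always far above background: beyond range
  c1 <- make_signal_curve(d, 1000 * exp(-0.01 * d), 10, 2)
  expect_identical(detectability_depth(c1), Inf)

  # monotone curve crossing the criterion exactly at a sample point
  crit <- 10 + 3 * 2
  raw <- crit + (20 - seq_along(d)) * 2.5
  c2 <- make_signal_curve(d, raw, 10, 2)
  expect_equal(detectability_depth(c2), d[20], tolerance = 1e-9)

  # exponential closed form: depth = ln(peak / crit) / mu
  mu <- 0.25; peak <- 500
  c3 <- make_signal_curve(d, peak * exp(-mu * d), 10, 2)
  expect_lt(abs(detectability_depth(c3) - log(peak / crit) / mu), 0.5)

  # FWHM curves are rejected
  fw <- c3; attr(fw, "value_kind") <- "fwhm"
  expect_error(detectability_depth(fw), "signal curve")
})

test_that("attenuation-coefficient fitting is exact and recovers mu", {
  d <- seq(1, 20, by = 0.25)
  exact <- make_signal_curve(d, exp(-0.05 * d), 0, 1)
  fit <- fit_attenuation_coefficient(exact)
  expect_equal(fit$mu_per_mm, 0.05, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  flat <- make_signal_curve(d, rep(2, length(d)), 0, 1)
  expect_equal(fit_attenuation_coefficient(flat)$mu_per_mm, 0,
               tolerance = 1e-12)

  neg <- make_signal_curve(d, exp(-0.05 * d), 0, 1)
  neg$value[4] <- -0.1
  expect_error(fit_attenuation_coefficient(neg), "nonpositive")

  # noiseless end-to-end: simulate -> flat-field -> profile -> fit,
  # recovered within 5% of the generator's mu_total = 0.08
  sp <- toy_phantom(blur_growth_per_mm = 0, background_fraction = 0)
  il <- vignette_illumination(120, 120, strength = 0.4)
  img <- render_fluorescence(sp, toy_cam(), il, noise = FALSE)
  calib <- render_photo(matrix(1, 120, 120), toy_cam(), il, 1,
                        noise = FALSE)
  calib$modality <- "calibration"
  corr <- apply_flatfield(img, make_flatfield(calib, 7.30))
  gt <- ground_truth_capillary(sp)
  cur <- attenuation_curve(corr, gt, list(x_mm = c(-15, 5),
                                          y_mm = c(6, 12)),
                           width_mm = 4)
  keep <- cur$depth_mm > 2 & cur$depth_mm < max(cur$depth_mm) - 2
  sub <- make_signal_curve(cur$depth_mm[keep],
                           attr(cur, "raw")[keep], 0, 1)
  fit2 <- fit_attenuation_coefficient(sub)
  expect_equal(fit2$mu_per_mm, 0.08, tolerance = 0.05)
})
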