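#' Planar CCD image container
#'
#' Bundles a pixel matrix (counts) with the acquisition metadata the pipeline
#' needs downstream: physical pixel size, exposure time and modality tag.
#' Rows index the lateral (y) direction, columns the axial (x) direction,
#' with pixel (1,1) at the upper-left and pixel centers on a grid centered
#' on the optical axis.
#'
#' @param pixels numeric matrix of nonnegative, finite counts.
#' @param pixel_size_mm physical pixel pitch at the bed plane, mm.
#' @param exposure_s exposure time in seconds.
#' @param modality one of `"photo"`, `"fluorescence"`, `"bioluminescence"`,
#'   `"spect_sum"`, `"calibration"`.
#' @param saturated logical flag set when any pixel reached the ADC ceiling.
#' @return an object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_mm, exposure_s, modality,
                    saturated = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stopf("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    .stopf("image pixels must be finite and nonnegative")
  .check_pos(pixel_size_mm, "pixel_size_mm")
  .check_pos(exposure_s, "exposure_s")
  modality <- match.arg(modality, c("photo", "fluorescence",
                                    "bioluminescence", "spect_sum",
                                    "calibration"))
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 exposure_s = exposure_s, modality = modality,
                 saturated = isTRUE(saturated)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.3g mm/px, %.3g s, %s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_mm, x$exposure_s,
              x$modality, if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Reconstructed emission volume
#'
#' Isotropic voxel grid with axes (x axial, y lateral, z depth below the
#' gel/animal top surface).
#'
#' @param voxels numeric 3-D array, nonnegative and finite.
#' @param voxel_size_mm isotropic voxel edge, mm (default 0.2).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size_mm = 0.2) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    .stopf("`voxels` must be a 3-D array")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    .stopf("voxel values must be finite and nonnegative")
  .check_pos(voxel_size_mm, "voxel_size_mm")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels, %.3g mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  invisible(x)
}

#' Digital phantom description
#'
#' Parametric stand-in for the tissue-simulating gel cylinder with an
#' obliquely inserted capillary uniformly filled with a fluorescent dye and
#' a gamma emitter. Coordinates: x axial along the cylinder axis (origin at
#' the gel center), y lateral, z depth below the top gel surface (z = 0 at
#' the surface, z = 2 * gel_radius_mm at the bottom).
#'
#' Optical tissue properties (hemoglobin + agarose) enter only through the
#' effective attenuation coefficients and the depth-dependent blur.
#'
#' @param gel_radius_mm,gel_length_mm cylinder geometry, mm.
#' @param capillary_inner_diameter_mm inner diameter of the capillary, mm.
#' @param capillary_fill_length_mm filled length of the capillary, mm.
#' @param inclination_deg angle from the horizontal bed plane, in (0, 90).
#' @param entry_point_mm 3-vector (x, y, z) where the filled section starts,
#'   just below the gel surface.
#' @param dye_concentration_uM dye concentration (arbitrary emission units).
#' @param activity_MBq_per_mL gamma activity concentration.
#' @param mu_ex_per_mm,mu_em_per_mm effective excitation / emission
#'   attenuation coefficients, per mm.
#' @param blur_sigma0_mm optical blur sigma at the surface, mm.
#' @param blur_growth_per_mm dimensionless growth of blur sigma per mm depth.
#' @param background_fraction autofluorescence + excitation-leakage level as
#'   a fraction of the unattenuated capillary peak signal.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(gel_radius_mm = 14, gel_length_mm = 70,
                         capillary_inner_diameter_mm = 0.9,
                         capillary_fill_length_mm = 60,
                         inclination_deg = 20,
                         entry_point_mm = c(-29, 0, 1.5),
                         dye_concentration_uM = 150,
                         activity_MBq_per_mL = 5,
                         mu_ex_per_mm = 0.05, mu_em_per_mm = 0.03,
                         blur_sigma0_mm = 0.25, blur_growth_per_mm = 0.035,
                         background_fraction = 0.05) {
  .check_pos(gel_radius_mm, "gel_radius_mm")
  .check_pos(gel_length_mm, "gel_length_mm")
  .check_pos(capillary_inner_diameter_mm, "capillary_inner_diameter_mm")
  .check_pos(capillary_fill_length_mm, "capillary_fill_length_mm")
  if (!.is_num1(inclination_deg) || inclination_deg <= 0 ||
      inclination_deg >= 90)
    .stopf("`inclination_deg` must lie strictly between 0 and 90")
  if (!is.numeric(entry_point_mm) || length(entry_point_mm) != 3L)
    .stopf("`entry_point_mm` must be a numeric 3-vector")
  .check_nonneg(dye_concentration_uM, "dye_concentration_uM")
  .check_nonneg(activity_MBq_per_mL, "activity_MBq_per_mL")
  .check_nonneg(mu_ex_per_mm, "mu_ex_per_mm")
  .check_nonneg(mu_em_per_mm, "mu_em_per_mm")
  .check_nonneg(blur_sigma0_mm, "blur_sigma0_mm")
  .check_nonneg(blur_growth_per_mm, "blur_growth_per_mm")
  .check_nonneg(background_fraction, "background_fraction")
  spec <- structure(list(
    gel_radius_mm = gel_radius_mm, gel_length_mm = gel_length_mm,
    capillary_inner_diameter_mm = capillary_inner_diameter_mm,
    capillary_fill_length_mm = capillary_fill_length_mm,
    inclination_deg = inclination_deg,
    entry_point_mm = as.numeric(entry_point_mm),
    dye_concentration_uM = dye_concentration_uM,
    activity_MBq_per_mL = activity_MBq_per_mL,
    mu_ex_per_mm = mu_ex_per_mm, mu_em_per_mm = mu_em_per_mm,
    blur_sigma0_mm = blur_sigma0_mm,
    blur_growth_per_mm = blur_growth_per_mm,
    background_fraction = background_fraction), class = "phantom_spec")
  .check_capillary_inside(spec)
  spec
}

# Capillary centerline must stay inside the gel cylinder over the fill
# length: |x| <= L/2 and y^2 + (z - R)^2 <= R^2 at both ends (the line is
# straight, the cross-section disc is convex, so endpoints suffice).
.check_capillary_inside <- function(spec) {
  ends <- .capillary_point(spec, c(0, spec$capillary_fill_length_mm))
  R <- spec$gel_radius_mm
  ok_x <- abs(ends[, 1]) <= spec$gel_length_mm / 2 + 1e-9
  ok_yz <- ends[, 2]^2 + (ends[, 3] - R)^2 <= R^2 + 1e-9
  if (!all(ok_x & ok_yz))
    .stopf("capillary centerline exits the gel within the fill length")
  invisible(TRUE)
}

# Points on the capillary centerline at arc length s (mm) from the entry.
.capillary_point <- function(spec, s) {
  th <- spec$inclination_deg * pi / 180
  p0 <- spec$entry_point_mm
  cbind(p0[1] + s * cos(th), p0[2] + 0 * s, p0[3] + s * sin(th))
}

#' CCD camera model
#'
#' @param pixel_size_mm pixel pitch at the bed plane (default 0.36 mm).
#' @param read_noise_counts Gaussian read noise standard deviation.
#' @param dark_current_counts_per_px_s thermal dark current rate.
#' @param adc_max_counts full-scale ADC value (16-bit default).
#' @param hot_pixel_rate_per_px_s rate of gamma-induced hot pixels per pixel
#'   per second per (MBq/mL) of activity present in the field of view.
#' @param quantum_scale photons-to-counts gain applied to all emission terms.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(pixel_size_mm = 0.36, read_noise_counts = 2,
                         dark_current_counts_per_px_s = 0.006,
                         adc_max_counts = 65535L,
                         hot_pixel_rate_per_px_s = 0,
                         quantum_scale = 1) {
  .check_pos(pixel_size_mm, "pixel_size_mm")
  .check_nonneg(read_noise_counts, "read_noise_counts")
  .check_nonneg(dark_current_counts_per_px_s, "dark_current_counts_per_px_s")
  if (!.is_num1(adc_max_counts) || adc_max_counts < 1)
    .stopf("`adc_max_counts` must be a positive integer")
  .check_nonneg(hot_pixel_rate_per_px_s, "hot_pixel_rate_per_px_s")
  .check_pos(quantum_scale, "quantum_scale")
  structure(list(pixel_size_mm = pixel_size_mm,
                 read_noise_counts = read_noise_counts,
                 dark_current_counts_per_px_s = dark_current_counts_per_px_s,
                 adc_max_counts = as.numeric(adc_max_counts),
                 hot_pixel_rate_per_px_s = hot_pixel_rate_per_px_s,
                 quantum_scale = quantum_scale),
            class = "camera_model")
}

#' Illumination field at the bed plane
#'
#' A smooth, strictly positive, unit-free 2-D pattern describing the
#' non-uniform excitation / white-light illumination.
#'
#' @param pattern numeric matrix, strictly positive and finite.
#' @return an object of class `illumination_field`.
#' @export
illumination_field <- function(pattern) {
  if (!is.matrix(pattern) || !is.numeric(pattern))
    .stopf("`pattern` must be a numeric matrix")
  if (any(!is.finite(pattern)) || any(pattern <= 0))
    .stopf("illumination pattern must be strictly positive and finite")
  structure(list(pattern = pattern), class = "illumination_field")
}

#' Parametric radially vignetted illumination
#'
#' Convenience generator for a realistic fibre-illuminator pattern: a smooth
#' radial falloff around an (optionally off-center) optical axis.
#'
#' @param n_row,n_col grid size in pixels.
#' @param strength falloff at the most distant corner, in `[0, 1)`;
#'   0.6 means the corner receives 40% of the central intensity.
#' @param center_frac fractional (row, col) position of the illumination axis.
#' @return an `illumination_field`.
#' @export
vignette_illumination <- function(n_row, n_col, strength = 0.5,
                                  center_frac = c(0.5, 0.5)) {
  if (!.is_num1(strength) || strength < 0 || strength >= 1)
    .stopf("`strength` must lie in [0, 1)")
  r0 <- center_frac[1] * n_row; c0 <- center_frac[2] * n_col
  rr <- outer(seq_len(n_row) - r0, rep(1, n_col))
  cc <- outer(rep(1, n_row), seq_len(n_col) - c0)
  d2 <- rr^2 + cc^2
  illumination_field(1 - strength * d2 / max(d2))
}

#' Gamma acquisition settings
#'
#' @param exposure_s scan time in seconds (default 1200 s, a 20-min scan).
#' @param n_angles number of parallel-beam projection angles.
#' @param detector_bins integer 2-vector (u, v) of detector bins.
#' @param photopeak_keV isotope photopeak (140 for Tc-99m, 171 for In-111).
#' @param energy_resolution_fwhm_frac photopeak FWHM as a fraction of the
#'   peak energy.
#' @param scatter_fraction fraction of all detected events that are scatter.
#' @param sensitivity_counts_per_MBq_s detected primary counts per MBq per s.
#' @param detector_sigma_mm intrinsic detector blur (Gaussian sigma).
#' @param scatter_energy_frac range of the scatter continuum as fractions
#'   of the photopeak energy; the density rises linearly toward the upper
#'   edge, mimicking the small-angle Compton pile-up below the photopeak.
#' @param scatter_smear_mm spatial smearing sigma of scattered events.
#' @param seed optional RNG seed stored with the settings.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(exposure_s = 1200, n_angles = 32,
                             detector_bins = c(64L, 64L),
                             photopeak_keV = 140,
                             energy_resolution_fwhm_frac = 0.05,
                             scatter_fraction = 0.25,
                             sensitivity_counts_per_MBq_s = 400,
                             detector_sigma_mm = 0.3,
                             scatter_energy_frac = c(0.45, 1.2),
                             scatter_smear_mm = 3,
                             seed = NULL) {
  .check_pos(exposure_s, "exposure_s")
  if (!.is_num1(n_angles) || n_angles < 1) .stopf("`n_angles` must be >= 1")
  if (length(detector_bins) != 2L || any(detector_bins < 1))
    .stopf("`detector_bins` must be two positive integers")
  .check_pos(photopeak_keV, "photopeak_keV")
  if (!.is_num1(energy_resolution_fwhm_frac) ||
      energy_resolution_fwhm_frac <= 0 || energy_resolution_fwhm_frac >= 1)
    .stopf("`energy_resolution_fwhm_frac` must lie in (0, 1)")
  if (!.is_num1(scatter_fraction) || scatter_fraction < 0 ||
      scatter_fraction >= 1)
    .stopf("`scatter_fraction` must lie in [0, 1)")
  .check_pos(sensitivity_counts_per_MBq_s, "sensitivity_counts_per_MBq_s")
  .check_nonneg(detector_sigma_mm, "detector_sigma_mm")
  structure(list(exposure_s = exposure_s, n_angles = as.integer(n_angles),
                 detector_bins = as.integer(detector_bins),
                 photopeak_keV = photopeak_keV,
                 energy_resolution_fwhm_frac = energy_resolution_fwhm_frac,
                 scatter_fraction = scatter_fraction,
                 sensitivity_counts_per_MBq_s = sensitivity_counts_per_MBq_s,
                 detector_sigma_mm = detector_sigma_mm,
                 scatter_energy_frac = scatter_energy_frac,
                 scatter_smear_mm = scatter_smear_mm,
                 seed = seed),
            class = "acquisition_spec")
}

#' Parallel-beam projection geometry
#'
#' Detector u axis lies in the (y, z) plane and rotates about the axial x
#' axis; v coincides with x. Bins are half-open `[lo, hi)` with the top edge
#' of the last bin closed.
#'
#' @param n_angles number of equally spaced angles over 180 degrees.
#' @param n_u,n_v number of detector bins.
#' @param bin_mm bin pitch (same for u and v).
#' @return an object of class `spect_geometry` with precomputed bin edges
#'   centered on the rotation axis.
#' @export
spect_geometry <- function(n_angles, n_u, n_v, bin_mm) {
  if (any(c(n_angles, n_u, n_v) < 1)) .stopf("geometry sizes must be >= 1")
  .check_pos(bin_mm, "bin_mm")
  structure(list(
    n_angles = as.integer(n_angles), n_u = as.integer(n_u),
    n_v = as.integer(n_v), bin_mm = bin_mm,
    angles_rad = seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)],
    u_edges = (seq_len(n_u + 1L) - 1L - n_u / 2) * bin_mm,
    v_edges = (seq_len(n_v + 1L) - 1L - n_v / 2) * bin_mm),
    class = "spect_geometry")
}

#' Similarity transform in bed-plane millimetres
#'
#' Maps a point `p` (mm, relative to the image center, x along columns and
#' y along rows) to `scale * R(rotation) %*% p + translation`.
#'
#' @param scale positive scale factor.
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param translation_mm numeric 2-vector (x, y) in mm.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 translation_mm = c(0, 0)) {
  .check_pos(scale, "scale")
  if (length(translation_mm) != 2L)
    .stopf("`translation_mm` must be a 2-vector")
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 translation_mm = as.numeric(translation_mm)),
            class = "similarity_transform")
}
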