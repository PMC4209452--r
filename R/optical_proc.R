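# Planar-image processing: flat-field illumination calibration, hot-pixel
# median filtering, exposure checking and rate normalization.

#' Convert between FWHM and Gaussian sigma
#'
#' `fwhm = 2 * sqrt(2 * ln 2) * sigma`, the definitional relation for a
#' Gaussian profile.
#'
#' @param fwhm_mm,sigma_mm positive lengths in mm.
#' @return the converted length in mm.
#' @export
fwhm_to_sigma <- function(fwhm_mm) {
  if (!.is_num1(fwhm_mm) || fwhm_mm <= 0)
    .stopf("`fwhm_mm` must be a single positive number")
  fwhm_mm / .FWHM_PER_SIGMA
}

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma_mm) {
  if (!.is_num1(sigma_mm) || sigma_mm <= 0)
    .stopf("`sigma_mm` must be a single positive number")
  sigma_mm * .FWHM_PER_SIGMA
}

#' Build a flat-field from an illumination calibration image
#'
#' The calibration image (white paper sheet under the working illumination)
#' is blurred with a Gaussian to suppress small-scale non-uniformities of
#' the paper itself, then normalized by scaling its maximum pixel value
#' to 1.
#'
#' @param calibration_image an `image2d` (modality photo, fluorescence or
#'   calibration).
#' @param blur_fwhm_mm FWHM of the smoothing Gaussian in mm (default
#'   7.30 mm).
#' @return an object of class `flatfield` with fields `pattern` (max
#'   exactly 1, strictly positive), `blur_fwhm_mm` and `source_modality`.
#' @export
make_flatfield <- function(calibration_image, blur_fwhm_mm = 7.30) {
  stopifnot(inherits(calibration_image, "image2d"))
  sigma_px <- fwhm_to_sigma(blur_fwhm_mm) / calibration_image$pixel_size_mm
  sm <- .blur2d(calibration_image$pixels, sigma_px)
  if (any(sm < 1e-6))
    .stopf(paste("calibration image is not strictly positive after",
                 "blurring; the flat field would not be invertible"))
  structure(list(pattern = sm / max(sm), blur_fwhm_mm = blur_fwhm_mm,
                 source_modality = calibration_image$modality),
            class = "flatfield")
}

#' Correct an image for non-uniform illumination
#'
#' Divides the image by the normalized flat-field pattern. Because the
#' pattern's maximum is 1, the output is everywhere greater than or equal
#' to the input.
#'
#' @param image an `image2d`.
#' @param flat a `flatfield` built on the same grid.
#' @return the corrected `image2d`; metadata are preserved.
#' @export
apply_flatfield <- function(image, flat) {
  stopifnot(inherits(image, "image2d"), inherits(flat, "flatfield"))
  if (!identical(dim(image$pixels), dim(flat$pattern)))
    .stopf("image (%d x %d) and flat field (%d x %d) shapes differ",
           nrow(image$pixels), ncol(image$pixels),
           nrow(flat$pattern), ncol(flat$pattern))
  out <- image
  out$pixels <- image$pixels / flat$pattern
  out
}

#' Median filter for gamma-induced hot pixels
#'
#' Replaces each pixel by the median of its `window_px` x `window_px`
#' neighborhood. For even windows the target pixel sits at 0-based offset
#' `ceiling(w/2) - 1` within the window and the median is the mean of the
#' two central order statistics; image borders are handled by edge
#' replication.
#'
#' @param image an `image2d`.
#' @param window_px window edge in pixels (default 4, >= 2).
#' @return the filtered `image2d`.
#' @export
median_filter_hot_pixels <- function(image, window_px = 4L) {
  stopifnot(inherits(image, "image2d"))
  w <- as.integer(window_px)
  if (w < 2L) .stopf("`window_px` must be >= 2")
  m <- image$pixels
  H <- nrow(m); W <- ncol(m)
  if (w > H || w > W) .stopf("window (%d) larger than image (%d x %d)",
                             w, H, W)
  lo <- -(ceiling(w / 2) - 1L)        # offsets covered by the window
  offs <- lo:(lo + w - 1L)
  pad <- max(abs(offs))
  # replicate-pad, then collect the w^2 shifted copies
  ri <- pmin(pmax(seq_len(H + 2L * pad) - pad, 1L), H)
  ci <- pmin(pmax(seq_len(W + 2L * pad) - pad, 1L), W)
  mp <- m[ri, ci]
  stack <- array(NA_real_, c(H, W, w * w))
  k <- 0L
  for (dr in offs) for (dc in offs) {
    k <- k + 1L
    stack[, , k] <- mp[(1L + pad + dr):(H + pad + dr),
                       (1L + pad + dc):(W + pad + dc)]
  }
  out <- image
  out$pixels <- apply(stack, c(1, 2), stats::median)
  out
}

#' Check an image against the exposure rule
#'
#' Exposure is acceptable when the brightest pixel exceeds half the full
#' ADC range without any pixel saturating.
#'
#' @param image an `image2d`.
#' @param adc_max full-scale ADC value.
#' @return `"saturated"` if any pixel is at or above `adc_max`; `"ok"` if
#'   the maximum exceeds `adc_max / 2`; `"underexposed"` otherwise.
#' @export
check_exposure <- function(image, adc_max = 65535) {
  stopifnot(inherits(image, "image2d"))
  mx <- max(image$pixels)
  if (mx >= adc_max) "saturated"
  else if (mx > adc_max / 2) "ok"
  else "underexposed"
}

#' Normalize an image to counts per second
#'
#' Divides by the exposure time so images taken at different exposures
#' (e.g. 500 ms fluorescence vs 60 s bioluminescence) become comparable;
#' the exposure metadata is set to 1 s.
#'
#' @param image an `image2d`.
#' @return the rate-normalized `image2d`.
#' @export
normalize_rate <- function(image) {
  stopifnot(inherits(image, "image2d"))
  out <- image
  out$pixels <- image$pixels / image$exposure_s
  out$exposure_s <- 1
  out
}
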