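# Fusion: thresholded color overlay of emission images on the grayscale
# photograph, and mask-moments similarity registration of the SPECT sum
# image to the photo (the in-silico replacement for manual contour
# matching).

.colormap_fun <- function(name) {
  ramp <- switch(name,
    hot  = grDevices::colorRamp(c("black", "red", "yellow", "white")),
    gray = grDevices::colorRamp(c("black", "white")),
    grDevices::colorRamp(grDevices::hcl.colors(64, name)))
  function(v) ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Thresholded color overlay
#'
#' Pixels whose signal is at or above `threshold_fraction` times the signal
#' maximum are shown colormapped; all other pixels show the grayscale base
#' image. A threshold of 0 overlays every pixel with positive signal. The
#' overlay is a pure function of its inputs, and the colored-pixel count is
#' non-increasing in the threshold.
#'
#' @param base an `image2d` (typically the photo), defining the grid.
#' @param signal an `image2d` on the same grid (resample first if needed).
#' @param threshold_fraction fraction of the signal maximum, in `[0, 1)`.
#' @param colormap colormap name (`"hot"`, `"gray"`, or any
#'   `grDevices::hcl.colors()` palette).
#' @param alpha blending weight of the color layer over the base, in
#'   `(0, 1]`.
#' @return an object of class `overlay_image`: field `rgb` is an
#'   `H x W x 3` array in `[0, 1]`, `colored` the logical overlay mask, and
#'   `provenance` records threshold, colormap and alpha.
#' @export
threshold_overlay <- function(base, signal, threshold_fraction = 0.3,
                              colormap = "hot", alpha = 1) {
  stopifnot(inherits(base, "image2d"), inherits(signal, "image2d"))
  if (!identical(dim(base$pixels), dim(signal$pixels)))
    .stopf("base and signal image shapes differ")
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    .stopf("`threshold_fraction` must lie in [0, 1)")
  H <- nrow(base$pixels); W <- ncol(base$pixels)
  bmax <- max(base$pixels)
  gray <- if (bmax > 0) base$pixels / bmax else base$pixels
  smax <- max(signal$pixels)
  mask <- if (smax > 0)
    signal$pixels >= threshold_fraction * smax & signal$pixels > 0
  else matrix(FALSE, H, W)
  rgb <- array(rep(gray, 3), c(H, W, 3))
  if (any(mask)) {
    cols <- .colormap_fun(colormap)(signal$pixels[mask] / smax)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[mask] <- alpha * cols[, ch] + (1 - alpha) * plane[mask]
      rgb[, , ch] <- plane
    }
  }
  structure(list(rgb = rgb, colored = mask,
                 provenance = list(threshold_fraction = threshold_fraction,
                                   colormap = colormap, alpha = alpha,
                                   base_modality = base$modality,
                                   signal_modality = signal$modality)),
            class = "overlay_image")
}

# Largest 4-connected component of a logical matrix (flood fill).
.largest_component <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  best <- 0L; best_size <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    size <- 0L
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      r <- (p - 1L) %% H + 1L
      c <- (p - 1L) %/% H + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < H) p + 1L,
              if (c > 1L) p - H, if (c < W) p + H)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
    if (size > best_size) { best <- cur; best_size <- size }
  }
  lab == best & best > 0L
}

# First and central second moments of a mask in centered mm coordinates.
.mask_moments <- function(mask, ps) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  x <- .col_to_mm(idx[, 2], W, ps)
  y <- .row_to_mm(idx[, 1], H, ps)
  cx <- mean(x); cy <- mean(y)
  list(area_mm2 = nrow(idx) * ps^2, centroid = c(cx, cy),
       mu20 = mean((x - cx)^2), mu02 = mean((y - cy)^2),
       mu11 = mean((x - cx) * (y - cy)))
}

.rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Estimate the SPECT-to-photo alignment from object contours
#'
#' Both images are thresholded at a fraction of their maximum, reduced to
#' their largest connected component, and a similarity transform is
#' estimated from the centroid offset, the principal-axis angle difference
#' and the square root of the mask area ratio. The transform maps signal
#' coordinates (mm, centered) onto base coordinates.
#'
#' @param signal an `image2d` containing one dominant foreground object
#'   (e.g. the SPECT sum image).
#' @param base the reference `image2d` (e.g. the photo).
#' @param mask_fraction threshold as a fraction of each image's maximum.
#' @return a [similarity_transform()].
#' @export
estimate_alignment <- function(signal, base, mask_fraction = 0.2) {
  stopifnot(inherits(signal, "image2d"), inherits(base, "image2d"))
  masks <- lapply(list(signal, base), function(im) {
    m <- im$pixels >= mask_fraction * max(im$pixels) & im$pixels > 0
    if (!any(m)) .stopf("empty foreground mask (%s image)", im$modality)
    .largest_component(m)
  })
  ms <- .mask_moments(masks[[1]], signal$pixel_size_mm)
  mb <- .mask_moments(masks[[2]], base$pixel_size_mm)
  theta <- function(m) 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)
  rot <- (theta(mb) - theta(ms)) * 180 / pi
  # principal axes are direction-ambiguous; fold into (-90, 90]
  rot <- ((rot + 90) %% 180) - 90
  s <- sqrt(mb$area_mm2 / ms$area_mm2)
  tr <- mb$centroid - s * as.vector(.rot2(rot) %*% ms$centroid)
  similarity_transform(scale = s, rotation_deg = rot, translation_mm = tr)
}

#' Resample an image onto a target grid under a similarity transform
#'
#' Each target pixel center is mapped back through the inverse transform
#' and the source image is sampled with bilinear interpolation;
#' out-of-field pixels are 0. Values are scaled by the transform Jacobian
#' and the pixel-area ratio so that total intensity of in-field content is
#' preserved.
#'
#' @param image the source `image2d`.
#' @param transform a [similarity_transform()] mapping source mm
#'   coordinates to target mm coordinates.
#' @param target an `image2d` whose grid (shape and pixel size) defines the
#'   output.
#' @return the resampled `image2d` (modality and exposure of the source).
#' @export
resample_to_grid <- function(image, transform, target) {
  stopifnot(inherits(image, "image2d"),
            inherits(transform, "similarity_transform"),
            inherits(target, "image2d"))
  Ht <- nrow(target$pixels); Wt <- ncol(target$pixels)
  pst <- target$pixel_size_mm
  Hs <- nrow(image$pixels); Ws <- ncol(image$pixels)
  pss <- image$pixel_size_mm
  xt <- .col_to_mm(rep(seq_len(Wt), each = Ht), Wt, pst)
  yt <- .row_to_mm(rep(seq_len(Ht), times = Wt), Ht, pst)
  Rinv <- .rot2(-transform$rotation_deg)
  px <- (xt - transform$translation_mm[1]) / transform$scale
  py <- (yt - transform$translation_mm[2]) / transform$scale
  xs <- Rinv[1, 1] * px + Rinv[1, 2] * py
  ys <- Rinv[2, 1] * px + Rinv[2, 2] * py
  v <- .interp2(image$pixels,
                .mm_to_row(ys, Hs, pss), .mm_to_col(xs, Ws, pss))
  v[is.na(v)] <- 0
  gain <- pst^2 / (transform$scale^2 * pss^2)
  out <- image
  out$pixels <- matrix(v * gain, Ht, Wt)
  out$pixel_size_mm <- pst
  out
}
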