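# File formats: single-strip uncompressed grayscale TIFF (16-bit unsigned
# or 32-bit float) with a JSON metadata sidecar, NIfTI-1 float32 volumes,
# and CSV event lists / profiles / curves. The TIFF and NIfTI codecs are
# deliberately minimal (this exact subset, nothing more) because no R
# reader for these formats is available in the target environment; they
# are cross-validated against Python tifffile/nibabel in the test suite.

.tiff_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {  # SHORT packed into the first 2 of 4 bytes
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Read and write planar images as TIFF with a JSON sidecar
#'
#' Images are stored as single-strip uncompressed grayscale TIFF,
#' little-endian: 16-bit unsigned when the pixel values are whole numbers
#' within the 16-bit range (bit-exact round trip), 32-bit float otherwise.
#' Acquisition metadata (`pixel_size_mm`, `exposure_s`, `modality`,
#' `saturated`, optionally `seed`) lives in a sidecar `<path>.json`;
#' reading fails if the sidecar or any required field is missing rather
#' than inventing defaults.
#'
#' @param image an `image2d`.
#' @param path output / input TIFF path.
#' @param seed optional seed recorded in the sidecar.
#' @return `write_image()` returns `path` invisibly; `read_image()` the
#'   `image2d`.
#' @export
write_image <- function(image, path, seed = NULL) {
  stopifnot(inherits(image, "image2d"))
  px <- image$pixels
  H <- nrow(px); W <- ncol(px)
  v <- as.vector(t(px))                       # TIFF is row-major
  use16 <- all(v == round(v)) && max(v) <= 65535
  nbytes <- H * W * (if (use16) 2L else 4L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + nbytes, con, size = 4, endian = "little")  # IFD offset
  if (use16) {
    iv <- as.integer(v)
    writeBin(ifelse(iv > 32767L, iv - 65536L, iv), con, size = 2,
             endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  }
  entries <- list(
    list(256, 4, 1, W), list(257, 4, 1, H),
    list(258, 3, 1, if (use16) 16 else 32),
    list(259, 3, 1, 1), list(262, 3, 1, 1),
    list(273, 4, 1, 8), list(277, 3, 1, 1),
    list(278, 4, 1, H), list(279, 4, 1, nbytes),
    list(339, 3, 1, if (use16) 1 else 3))
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) .tiff_entry(con, e[[1]], e[[2]], e[[3]], e[[4]])
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  meta <- list(pixel_size_mm = image$pixel_size_mm,
               exposure_s = image$exposure_s, modality = image$modality,
               saturated = image$saturated)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    .stopf("missing metadata sidecar %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  for (f in c("pixel_size_mm", "exposure_s", "modality"))
    if (is.null(meta[[f]])) .stopf("sidecar %s lacks field `%s`", sidecar, f)
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 2) != "II") .stopf("%s: not a little-endian TIFF", path)
  readBin(con, integer(), 1, size = 2, endian = "little")
  ifd_off <- readBin(con, integer(), 1, size = 4, endian = "little")
  seek(con, ifd_off)
  n <- readBin(con, integer(), 1, size = 2, endian = "little")
  tags <- list()
  for (i in seq_len(n)) {
    tag <- readBin(con, integer(), 1, size = 2, signed = FALSE,
                   endian = "little")
    type <- readBin(con, integer(), 1, size = 2, endian = "little")
    readBin(con, integer(), 1, size = 4, endian = "little")  # count
    val <- if (type == 3L) {
      x <- readBin(con, integer(), 1, size = 2, signed = FALSE,
                   endian = "little")
      readBin(con, integer(), 1, size = 2, endian = "little")
      x
    } else readBin(con, integer(), 1, size = 4, endian = "little")
    tags[[as.character(tag)]] <- val
  }
  W <- tags[["256"]]; H <- tags[["257"]]
  bps <- tags[["258"]]; fmt <- tags[["339"]]
  if (is.null(W) || is.null(H) || !identical(tags[["259"]], 1L))
    .stopf("%s: unsupported TIFF layout", path)
  seek(con, tags[["273"]])
  v <- if (identical(fmt, 3L)) {
    readBin(con, numeric(), H * W, size = 4, endian = "little")
  } else {
    x <- readBin(con, integer(), H * W, size = bps / 8, signed = FALSE,
                 endian = "little")
    as.numeric(x)
  }
  image2d(t(matrix(v, W, H)), meta$pixel_size_mm, meta$exposure_s,
          meta$modality, saturated = isTRUE(meta$saturated))
}

#' Read and write volumes as NIfTI-1
#'
#' Float32 single-file NIfTI-1 (`n+1` magic) with the isotropic voxel size
#' in `pixdim`; reading a file with anisotropic voxels is an error.
#'
#' @param volume a [volume3d()].
#' @param path output / input `.nii` path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` the
#'   `volume3d`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  d <- dim(volume$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  wB <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wB(348L, 4)
  writeBin(raw(36), con)                       # unused header fields
  wB(as.integer(c(3, d, 1, 1, 1, 1)), 2)       # dim[8]
  wB(numeric(3), 4)                            # intent_p1..p3
  wB(0L, 2)                                    # intent_code
  wB(16L, 2); wB(32L, 2); wB(0L, 2)            # datatype, bitpix, slice_start
  wB(c(1, rep(volume$voxel_size_mm, 3), 0, 0, 0, 0), 4)  # pixdim[8]
  wB(352, 4)                                   # vox_offset
  wB(c(1, 0), 4)                               # scl_slope, scl_inter
  wB(0L, 2)                                    # slice_end
  writeBin(as.raw(c(0, 2)), con)               # slice_code, xyzt_units (mm)
  wB(numeric(4), 4)                            # cal_max..toffset
  wB(integer(2), 4)                            # glmax, glmin
  writeBin(raw(104), con)                      # descrip, aux_file
  wB(integer(2), 2)                            # qform_code, sform_code
  wB(numeric(6), 4)                            # quaternions and offsets
  wB(numeric(12), 4)                           # srow
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                        # no extensions
  wB(as.numeric(volume$voxels), 4)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rB <- function(what, n, size) readBin(con, what, n, size = size,
                                        endian = "little")
  if (rB(integer(), 1, 4) != 348L) .stopf("%s: not a NIfTI-1 file", path)
  readBin(con, raw(), 36)
  dims <- rB(integer(), 8, 2)
  if (dims[1] != 3L) .stopf("%s: expected a 3-D volume, got %d dims",
                            path, dims[1])
  rB(numeric(), 3, 4); rB(integer(), 1, 2)
  datatype <- rB(integer(), 1, 2)
  if (datatype != 16L) .stopf("%s: only float32 NIfTI is supported", path)
  rB(integer(), 2, 2)
  pixdim <- rB(numeric(), 8, 4)
  vox <- pixdim[2:4]
  if (diff(range(vox)) > 1e-5 * mean(vox))
    .stopf("%s: anisotropic voxels (%.4g, %.4g, %.4g mm) are not supported",
           path, vox[1], vox[2], vox[3])
  vox_offset <- rB(numeric(), 1, 4)
  seek(con, vox_offset)
  n <- prod(dims[2:4])
  v <- rB(numeric(), n, 4)
  if (length(v) != n) .stopf("%s: truncated data section", path)
  volume3d(array(v, dims[2:4]), signif(mean(vox), 7))
}

#' Read and write list-mode event CSV files
#'
#' Schema: `angle_index,u_mm,v_mm,energy_keV` (angle 0-based).
#'
#' @param events an `event_list` data frame.
#' @param path CSV path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   `event_list`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("angle_index", "u_mm", "v_mm",
                                             "energy_keV")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("angle_index", "u_mm", "v_mm", "energy_keV")
  if (!identical(names(ev), need))
    .stopf("%s: expected columns %s", path, paste(need, collapse = ","))
  class(ev) <- c("event_list", "data.frame")
  ev
}

#' Write a line profile or depth curve as CSV
#'
#' Profiles use the schema `position_mm,value`; curves
#' `depth_mm,value,value_kind`.
#'
#' @param x a `line_profile` or `depth_curve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  df <- if (inherits(x, "line_profile")) {
    data.frame(position_mm = x$positions_mm, value = x$values)
  } else if (inherits(x, "depth_curve")) {
    data.frame(depth_mm = x$depth_mm, value = x$value,
               value_kind = attr(x, "value_kind"))
  } else .stopf("`x` must be a line_profile or depth_curve")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
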