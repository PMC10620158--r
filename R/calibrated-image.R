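#' Calibrated single-channel image
#'
#' The unit-bearing raster all assays consume: a 2-D non-negative intensity
#' matrix (arbitrary units) plus a pixel-size calibration in micrometres per
#' pixel. Coordinates are 0-based `(row, col)` with the origin at the top-left
#' pixel; all physical lengths elsewhere in the package are in micrometres.
#'
#' @param pixels Numeric matrix of non-negative intensities (a.u.).
#' @param pixel_size_um Pixel size in micrometres per pixel; must be supplied
#'   explicitly — no operation in the package ever guesses a calibration.
#' @param channel Optional channel label (e.g. `"phalloidin"`, `"hoechst"`).
#' @param bit_depth Nominal acquisition bit depth, 8 or 16.
#'
#' @return An object of class `calibrated_image`: the pixel matrix with
#'   calibration attributes.
#' @examples
#' img <- calibrated_image(matrix(0, 32, 32), pixel_size_um = 0.5)
#' dim(img)
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel = "unknown",
                             bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    rlang::abort("`pixels` must be a non-empty numeric matrix (one channel).")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    rlang::abort("`pixels` must be finite and non-negative.")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  if (!bit_depth %in% c(8L, 16L)) {
    rlang::abort("`bit_depth` must be 8 or 16.")
  }
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            channel = as.character(channel),
            bit_depth = as.integer(bit_depth),
            class = c("calibrated_image", "matrix", "array"))
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, channel '%s', %d-bit\n",
              nrow(x), ncol(x), pixel_size_um(x), attr(x, "channel"),
              attr(x, "bit_depth")))
  cat(sprintf("  intensity range [%.4g, %.4g] a.u.\n", min(x), max(x)))
  invisible(x)
}

#' @rdname calibrated_image
#' @param x A `calibrated_image`.
#' @export
pixel_size_um <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) rlang::abort("Image carries no pixel-size calibration.")
  ps
}

as_pixel_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  y
}

#' Read a single-channel TIFF with an explicit calibration
#'
#' Integer sample values are read as-is, so a write/read cycle through
#' [save_image()] is lossless for integer-valued images. RGB or multi-channel
#' files are rejected: export each channel to its own file upstream.
#'
#' @param path Path to an 8- or 16-bit single-channel TIFF.
#' @param pixel_size_um Micrometres per pixel. If `NULL` (default) the reader
#'   looks for a JSON sidecar `<path>.json` with a `pixel_size_um` field and
#'   errors if neither source provides a calibration.
#' @param channel Channel label attached to the result.
#' @return A [calibrated_image()].
#' @export
load_image <- function(path, pixel_size_um = NULL, channel = "unknown") {
  if (!file.exists(path)) rlang::abort(sprintf("No such file: '%s'", path))
  px <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(px)) == 3L) {
    rlang::abort(sprintf(
      "'%s' has %d channels; this pipeline reads single-channel images. Export each channel to its own file.",
      path, dim(px)[3]))
  }
  bits <- attr(px, "bits.per.sample") %||% 16L
  if (!bits %in% c(8L, 16L)) {
    rlang::abort(sprintf("'%s' is %d-bit; only 8- and 16-bit rasters are supported.", path, bits))
  }
  sidecar <- paste0(path, ".json")
  if (is.null(pixel_size_um) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
  }
  if (is.null(pixel_size_um)) {
    rlang::abort(sprintf(
      "No pixel size for '%s': pass `pixel_size_um` or provide a '%s' sidecar. Calibrations are never guessed.",
      path, basename(sidecar)))
  }
  calibrated_image(matrix(as.numeric(px), nrow(px), ncol(px)),
                   pixel_size_um = pixel_size_um, channel = channel,
                   bit_depth = as.integer(bits))
}

#' Write a calibrated image as TIFF plus a JSON sidecar
#'
#' Pixels are rounded to integers and written at the image's bit depth; the
#' sidecar records `pixel_size_um`, the channel, and any extra metadata
#' (e.g. the generator seed) so a round trip restores the calibration.
#'
#' @param image A [calibrated_image()].
#' @param path Output TIFF path.
#' @param metadata Named list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, metadata = list()) {
  ps <- pixel_size_um(image)
  bits <- attr(image, "bit_depth") %||% 16L
  maxval <- 2^bits - 1
  px <- round(as_pixel_matrix(image))
  if (max(px) > maxval) {
    rlang::abort(sprintf("Intensities exceed the %d-bit range (max %.0f > %d).",
                         bits, max(px), maxval))
  }
  tiff::writeTIFF(px / maxval, path, bits.per.sample = as.integer(bits))
  meta <- c(list(pixel_size_um = ps, channel = attr(image, "channel"),
                 bit_depth = bits), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
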