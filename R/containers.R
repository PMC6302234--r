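# Lightweight S3 containers for single-channel images and binary masks.

#' Single-channel grayscale image
#'
#' A `channel_image` wraps one grayscale channel of one tile together with its
#' physical pixel size and channel label. Intensities are stored in native
#' units (e.g. 0-65535 for 16-bit fluorescent channels, 0-255 for 8-bit
#' chromogenic channels).
#'
#' @param pixels numeric matrix of non-negative intensities, `[row, col]`.
#' @param pixel_size_um physical pixel size in micrometers (> 0).
#' @param channel channel label, e.g. `"CD68"` or `"DAPI"`.
#' @param tile_id identifier of the tile the channel belongs to.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um, channel, tile_id = "tile") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1, pixel_size_um > 0,
    nrow(pixels) >= 1, ncol(pixels) >= 1
  )
  if (any(pixels < 0)) stop("channel_image: intensities must be non-negative")
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      channel = as.character(channel),
      tile_id = as.character(tile_id)
    ),
    class = "channel_image"
  )
}

#' Binary marker mask
#'
#' A `marker_mask` is a binary positive-pixel mask for one marker or a derived
#' pixel class, carrying the geometry (pixel size) of its source channel.
#'
#' @param pixels logical matrix, `TRUE` where the marker is positive.
#' @param pixel_size_um physical pixel size in micrometers (> 0).
#' @param label marker or class label.
#' @param tile_id identifier of the source tile.
#' @return An object of class `marker_mask`.
#' @export
marker_mask <- function(pixels, pixel_size_um, label, tile_id = "tile") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    pixels <- pixels != 0
  }
  stopifnot(
    is.numeric(pixel_size_um), length(pixel_size_um) == 1, pixel_size_um > 0,
    nrow(pixels) >= 1, ncol(pixels) >= 1
  )
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      label = as.character(label),
      tile_id = as.character(tile_id)
    ),
    class = "marker_mask"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %s / %s: %d x %d px @ %.3g um/px, range [%g, %g]\n",
    x$tile_id, x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
print.marker_mask <- function(x, ...) {
  cat(sprintf(
    "<marker_mask> %s / %s: %d x %d px @ %.3g um/px, %d positive px (%.2f%%)\n",
    x$tile_id, x$label, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    positive_count(x), 100 * positive_count(x) / length(x$pixels)
  ))
  invisible(x)
}

#' Number of positive pixels in a mask
#' @param mask a [marker_mask()].
#' @return integer count of `TRUE` pixels.
#' @export
positive_count <- function(mask) {
  stopifnot(inherits(mask, "marker_mask"))
  sum(mask$pixels)
}

# Stop unless two image-like objects share dimensions and pixel size. Used at
# every hand-off so no stage silently consumes mismatched geometry.
check_same_geometry <- function(a, b, what = "operands") {
  da <- dim(a$pixels)
  db <- dim(b$pixels)
  if (!identical(da, db)) {
    stop(sprintf(
      "geometry mismatch between %s: %dx%d vs %dx%d",
      what, da[1], da[2], db[1], db[2]
    ))
  }
  if (abs(a$pixel_size_um - b$pixel_size_um) > 1e-9) {
    stop(sprintf(
      "pixel size mismatch between %s: %g vs %g um",
      what, a$pixel_size_um, b$pixel_size_um
    ))
  }
  invisible(TRUE)
}

# TIFF I/O -------------------------------------------------------------------

#' Read a single-channel TIFF as a channel image
#'
#' @param path path to a single-channel grayscale TIFF.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param channel channel label.
#' @param tile_id tile identifier (defaults to the file stem).
#' @return A [channel_image()] in native integer units.
#' @export
read_channel_tiff <- function(path, pixel_size_um, channel,
                              tile_id = tools::file_path_sans_ext(basename(path))) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] != 1) stop("expected a single-channel TIFF: ", path)
    px <- px[, , 1]
  }
  channel_image(px, pixel_size_um, channel, tile_id)
}

#' Write a channel image as a single-channel TIFF
#'
#' @param image a [channel_image()].
#' @param path output path.
#' @param bits_per_sample 8 or 16; intensities are assumed to span the native
#'   range of that depth.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path, bits_per_sample = 16) {
  stopifnot(inherits(image, "channel_image"), bits_per_sample %in% c(8, 16))
  scale <- 2^bits_per_sample - 1
  px <- pmin(pmax(image$pixels / scale, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a binary mask from an 8-bit TIFF (nonzero = positive)
#' @inheritParams read_channel_tiff
#' @param label mask label.
#' @return A [marker_mask()].
#' @export
read_mask_tiff <- function(path, pixel_size_um, label,
                           tile_id = tools::file_path_sans_ext(basename(path))) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) px <- px[, , 1]
  marker_mask(px > 0, pixel_size_um, label, tile_id)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask a [marker_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "marker_mask"))
  tiff::writeTIFF(ifelse(mask$pixels, 1, 0), path, bits.per.sample = 8)
  invisible(path)
}
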