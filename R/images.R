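# Image containers and I/O.
#
# Images are integer arrays [row, col, channel] with values in 0..255;
# masks are integer matrices [row, col] with labels in 0..3. EBImage stores
# pixels [x = col, y = row, channel], so every call across that boundary
# transposes the spatial dimensions.

MASK_CLASSES <- c(background = 0L, target = 1L, body = 2L, awn = 3L)

# Per-channel normalization constants applied before every network forward
# pass (ImageNet-style; recorded with each model artifact).
NORM_MEAN <- c(0.485, 0.456, 0.406)
NORM_SD <- c(0.229, 0.224, 0.225)

#' Validate an RGB image array
#'
#' @param image numeric array `H x W x 3` with values in `[0, 255]`.
#' @return The image, invisibly.
#' @keywords internal
check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  if (anyNA(image)) stop("`image` contains NA values", call. = FALSE)
  invisible(image)
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("`mask` must be an H x W integer matrix", call. = FALSE)
  bad <- !(mask %in% MASK_CLASSES)
  if (any(bad)) stop("mask labels must lie in {0, 1, 2, 3}", call. = FALSE)
  invisible(mask)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Round half away from zero; base round() is round-half-even, which would make
# intensity arithmetic (e.g. brightness scaling) depend on value parity.
round_half_up <- function(x) floor(x + 0.5)

#' Read / write 8-bit RGB images and index masks as PNG
#'
#' Images round-trip exactly: an 8-bit value v is stored as v/255 and
#' recovered as round(255 * v/255) = v. Masks are stored as single-channel
#' PNGs with gray levels equal to the class index (0-3).
#'
#' @param path file path.
#' @param image `H x W x 3` array in 0..255.
#' @param mask `H x W` integer matrix with values 0..3.
#' @return `read_image_png()` returns an integer `H x W x 3` array;
#'   `read_mask_png()` an integer matrix.
#' @export
write_image_png <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim(a))
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}

#' Resize an image or mask
#'
#' Images are resampled bilinearly; masks with nearest neighbour so that label
#' values are preserved.
#'
#' @param image `H x W x 3` array (0..255) or, for `resize_mask()`, an integer
#'   matrix of class labels.
#' @param height,width target size in pixels.
#' @return Resized array/matrix of the requested size.
#' @export
resize_image <- function(image, height, width) {
  check_image(image)
  eb <- EBImage::Image(aperm(image, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::resize(eb, w = width, h = height, filter = "bilinear")
  arr <- aperm(EBImage::imageData(out), c(2, 1, 3))
  array(as.integer(round_half_up(clamp255(arr * 255))), dim(arr))
}

#' @rdname resize_image
#' @export
resize_mask <- function(mask, height, width) {
  check_mask(mask)
  eb <- EBImage::Image(t(mask))
  out <- EBImage::resize(eb, w = width, h = height, filter = "none")
  m <- t(EBImage::imageData(out))
  matrix(as.integer(m), nrow(m), ncol(m))
}

# Normalize an 8-bit image to the zero-mean unit-ish scale used by the
# networks: (v/255 - mean_c) / sd_c per channel.
normalize_image <- function(image) {
  x <- image / 255
  for (c in 1:3) x[, , c] <- (x[, , c] - NORM_MEAN[c]) / NORM_SD[c]
  x
}
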