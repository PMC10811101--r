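# Spike-body crop preparation.
#
# From a segmented scene: take the tight bounding rectangle of the
# spike-body class, black out everything that is not spike body inside it,
# and cut classifier-ready square crops (full-rectangle resize, random small
# crops, or central medium/large windows). Small crops with too little spike
# coverage are discarded.

#' Crop-preparation configuration
#'
#' @param strategy one of `"resize_full"`, `"small_random"`,
#'   `"medium_central"`, `"large_central"`.
#' @param small,medium,large,resize_target crop side lengths in px. Defaults
#'   follow the scales used for full-resolution spike photographs (128, 512,
#'   864, 512); desk-scale work passes smaller values.
#' @param n_small_crops random small crops attempted per image.
#' @param min_spike_fraction crops whose spike-body pixel count falls below
#'   this fraction of the crop area (nearest-integer pixel budget, boundary
#'   inclusive) are discarded. Default 0.30.
#' @param seed RNG seed for the random small-crop offsets.
#' @return Object of class `crop_config`.
#' @export
crop_config <- function(strategy = c("medium_central", "resize_full",
                                     "small_random", "large_central"),
                        small = 128L, medium = 512L, large = 864L,
                        resize_target = 512L, n_small_crops = 8L,
                        min_spike_fraction = 0.30, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(small > 0, medium > 0, large > 0, resize_target > 0,
            min_spike_fraction >= 0, min_spike_fraction <= 1)
  structure(list(strategy = strategy, small = as.integer(small),
                 medium = as.integer(medium), large = as.integer(large),
                 resize_target = as.integer(resize_target),
                 n_small_crops = as.integer(n_small_crops),
                 min_spike_fraction = min_spike_fraction,
                 seed = as.integer(seed)),
            class = "crop_config")
}

#' Tight bounding box of the spike body
#'
#' Half-open box `[row_min, row_max) x [col_min, col_max)` (1-based lower
#' bounds) containing every spike-body (class 2) pixel.
#'
#' @param mask integer class mask.
#' @return Object of class `sg_bbox`: list(row_min, col_min, row_max, col_max).
#' @export
extract_bbox <- function(mask) {
  idx <- which(mask == MASK_CLASSES[["body"]], arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no spike-body pixels in mask (empty-spike)", call. = FALSE)
  structure(list(row_min = min(idx[, 1]), col_min = min(idx[, 2]),
                 row_max = max(idx[, 1]) + 1L, col_max = max(idx[, 2]) + 1L),
            class = "sg_bbox")
}

bbox_rows <- function(b) b$row_min:(b$row_max - 1L)
bbox_cols <- function(b) b$col_min:(b$col_max - 1L)

#' Crop to the bounding box and black out non-spike pixels
#'
#' Inside the box, pixels whose mask class is not spike body are set to
#' (0, 0, 0); spike-body pixels are kept unchanged. Idempotent.
#'
#' @param image `H x W x 3` array.
#' @param mask matching class mask.
#' @param bbox an [extract_bbox()] result for the same mask.
#' @return List with `image` (cropped, background-blacked array) and `mask`
#'   (cropped class mask).
#' @export
blackout_background <- function(image, mask, bbox = extract_bbox(mask)) {
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask dimensions differ", call. = FALSE)
  rows <- bbox_rows(bbox); cols <- bbox_cols(bbox)
  sub_img <- image[rows, cols, , drop = FALSE]
  sub_mask <- mask[rows, cols, drop = FALSE]
  keep <- sub_mask == MASK_CLASSES[["body"]]
  for (ch in 1:3) {
    pl <- sub_img[, , ch]
    pl[!keep] <- 0
    sub_img[, , ch] <- pl
  }
  list(image = sub_img, mask = sub_mask)
}

# Cut a square window of side `size` whose top-left corner is at (r0, c0)
# (may extend beyond the rectangle); out-of-rectangle pixels are black
# (mask: background).
window_crop <- function(image, mask, r0, c0, size) {
  out_img <- array(0, c(size, size, 3))
  out_mask <- matrix(0L, size, size)
  H <- dim(image)[1]; W <- dim(image)[2]
  rr <- r0:(r0 + size - 1L); cc <- c0:(c0 + size - 1L)
  rin <- which(rr >= 1 & rr <= H); cin <- which(cc >= 1 & cc <= W)
  if (length(rin) && length(cin)) {
    out_img[rin, cin, ] <- image[rr[rin], cc[cin], , drop = FALSE]
    out_mask[rin, cin] <- mask[rr[rin], cc[cin], drop = FALSE]
  }
  list(image = out_img, mask = out_mask, offset_row = r0, offset_col = c0)
}

#' Cut classifier-ready square crops from a spike rectangle
#'
#' Strategies: `resize_full` resamples the whole rectangle bilinearly to
#' `resize_target` (aspect ratio not preserved); `small_random` draws up to
#' `n_small_crops` random windows lying fully inside the rectangle and then
#' filters them by spike fraction ([filter_crops()]); `medium_central` /
#' `large_central` cut one window of the respective size centered on the
#' rectangle center (`floor((min + max) / 2)` rounding), padding any region
#' outside the rectangle with black.
#'
#' @param spike_rect background-blacked rectangle from
#'   [blackout_background()] (`$image`).
#' @param cfg a [crop_config()].
#' @param mask_rect the matching cropped mask (`$mask`).
#' @return List of crops, each `list(image, mask, offset_row, offset_col,
#'   spike_fraction)`. `small_random` on a rectangle smaller than the crop
#'   size returns an empty list with a warning.
#' @export
make_crops <- function(spike_rect, cfg, mask_rect) {
  H <- dim(spike_rect)[1]; W <- dim(spike_rect)[2]
  if (H == 0 || W == 0) stop("empty spike rectangle", call. = FALSE)
  frac <- function(m) mean(m == MASK_CLASSES[["body"]])
  if (cfg$strategy == "resize_full") {
    img <- resize_image(spike_rect, cfg$resize_target, cfg$resize_target)
    msk <- resize_mask(mask_rect, cfg$resize_target, cfg$resize_target)
    return(list(list(image = img, mask = msk, offset_row = 1L, offset_col = 1L,
                     spike_fraction = frac(msk))))
  }
  if (cfg$strategy == "small_random") {
    s <- cfg$small
    if (H < s || W < s) {
      warning("spike rectangle smaller than the small-crop size; no crops",
              call. = FALSE)
      return(list())
    }
    set.seed(cfg$seed)
    crops <- lapply(seq_len(cfg$n_small_crops), function(i) {
      r0 <- sample.int(H - s + 1L, 1L)
      c0 <- sample.int(W - s + 1L, 1L)
      cr <- window_crop(spike_rect, mask_rect, r0, c0, s)
      cr$spike_fraction <- frac(cr$mask)
      cr
    })
    return(filter_crops(crops, min_spike_fraction = cfg$min_spike_fraction))
  }
  size <- if (cfg$strategy == "medium_central") cfg$medium else cfg$large
  # center = floor((min + max) / 2); a window of matching parity reproduces
  # the rectangle exactly when sizes coincide
  ctr_r <- floor((1 + H) / 2); ctr_c <- floor((1 + W) / 2)
  r0 <- ctr_r - (size - 1L) %/% 2L
  c0 <- ctr_c - (size - 1L) %/% 2L
  cr <- window_crop(spike_rect, mask_rect, as.integer(r0), as.integer(c0), size)
  cr$spike_fraction <- frac(cr$mask)
  list(cr)
}

#' Filter crops by spike-pixel fraction
#'
#' Crops with too few spike-body pixels are discarded. The threshold is
#' applied as a pixel budget: a crop of `N` pixels is kept when its
#' spike-body pixel count is at least `min_spike_fraction * N` rounded to
#' the nearest integer, so a crop sitting exactly at the nominal percentage
#' (e.g. 4,915 of 16,384 pixels for the default 30%) is kept and one pixel
#' fewer is discarded.
#'
#' @param crops list of crops as produced by [make_crops()], each carrying a
#'   `mask` and/or a precomputed `spike_fraction`.
#' @param mask_crops optional list of masks overriding `crops[[i]]$mask`.
#' @param min_spike_fraction the threshold (default 0.30).
#' @return The kept crops.
#' @export
filter_crops <- function(crops, mask_crops = NULL, min_spike_fraction = 0.30) {
  keep <- vapply(seq_along(crops), function(i) {
    m <- if (!is.null(mask_crops)) mask_crops[[i]] else crops[[i]]$mask
    if (!is.null(m)) {
      n <- length(m)
      sum(m == MASK_CLASSES[["body"]]) >= round_half_up(min_spike_fraction * n)
    } else {
      crops[[i]]$spike_fraction >= min_spike_fraction
    }
  }, logical(1))
  crops[keep]
}
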