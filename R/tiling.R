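# Tiled inference over large scenes.
#
# Scenes are split into square tiles laid on a stride grid; the final offset
# along each axis is clamped flush with the border so the union of tiles
# covers every pixel. Per-class soft weights predicted on each tile are
# averaged per pixel over all tiles covering it (coverage is 4 for interior
# pixels under the default 512/256 tiling), and the per-pixel argmax gives
# the class mask.

#' Tiling configuration
#'
#' @param tile_size tile side in px (default 512).
#' @param stride tile grid stride in px (default 256, i.e. half-tile overlap).
#' @return Object of class `tiling_config`.
#' @export
tiling_config <- function(tile_size = 512L, stride = 256L) {
  if (stride <= 0 || stride > tile_size)
    stop("stride must satisfy 0 < stride <= tile_size", call. = FALSE)
  structure(list(tile_size = as.integer(tile_size), stride = as.integer(stride)),
            class = "tiling_config")
}

# Offsets (0-based) of tiles along one axis of length `n`: multiples of the
# stride, with the last offset clamped to n - tile so the final tile sits
# flush with the border; duplicates removed.
tile_offsets <- function(n, tile, stride) {
  if (n <= tile) return(0L)
  off <- seq.int(0L, n - 1L, by = stride)
  off <- off[off + tile <= n]
  last <- n - tile
  unique(as.integer(c(off, last)))
}

#' Split an image into overlapping tiles
#'
#' Images smaller than the tile size along either axis are symmetrically
#' zero-padded to the tile size; the padding amounts are recorded so
#' aggregation can crop them off again.
#'
#' @param image `H x W x 3` array (or `H x W` matrix, tiled identically).
#' @param tiling a [tiling_config()].
#' @return Object of class `sg_tileset`: list with `offsets` (data.frame of
#'   0-based `row`, `col`), `tiles` (list of tile arrays), `height`, `width`
#'   (original size), `pad` (top, left padding applied) and `tile_size`.
#' @export
tile_image <- function(image, tiling = tiling_config()) {
  d <- dim(image)
  if (is.null(d) || any(d[1:2] == 0)) stop("empty image", call. = FALSE)
  H <- d[1]; W <- d[2]
  ts <- tiling$tile_size
  pad_r <- max(0L, ts - H); pad_c <- max(0L, ts - W)
  pad_top <- pad_r %/% 2L; pad_left <- pad_c %/% 2L
  Hp <- H + pad_r; Wp <- W + pad_c
  if (pad_r > 0 || pad_c > 0) {
    if (length(d) == 3L) {
      padded <- array(0, c(Hp, Wp, d[3]))
      padded[pad_top + seq_len(H), pad_left + seq_len(W), ] <- image
    } else {
      padded <- matrix(0, Hp, Wp)
      padded[pad_top + seq_len(H), pad_left + seq_len(W)] <- image
    }
    image <- padded
  }
  ro <- tile_offsets(Hp, ts, tiling$stride)
  co <- tile_offsets(Wp, ts, tiling$stride)
  offsets <- expand.grid(row = ro, col = co, KEEP.OUT.ATTRS = FALSE)
  offsets <- offsets[order(offsets$row, offsets$col), , drop = FALSE]
  rownames(offsets) <- NULL
  tiles <- lapply(seq_len(nrow(offsets)), function(i) {
    r0 <- offsets$row[i]; c0 <- offsets$col[i]
    if (length(dim(image)) == 3L)
      image[r0 + seq_len(ts), c0 + seq_len(ts), , drop = FALSE]
    else
      image[r0 + seq_len(ts), c0 + seq_len(ts), drop = FALSE]
  })
  structure(list(offsets = offsets, tiles = tiles, height = H, width = W,
                 pad = c(top = pad_top, left = pad_left),
                 padded_height = Hp, padded_width = Wp,
                 tile_size = ts),
            class = "sg_tileset")
}

#' Average per-tile soft predictions into a scene-level soft prediction
#'
#' Each pixel's class weight is the arithmetic mean of that class's weight
#' over all tiles covering the pixel. Padded margins introduced by
#' [tile_image()] are cropped off.
#'
#' @param tile_maps list of `tile_size x tile_size x n_class` weight arrays,
#'   aligned with `tileset$offsets`.
#' @param tileset the [tile_image()] result the maps were predicted from.
#' @return Object of class `sg_soft`: list with `weights`
#'   (`H x W x n_class`) and `coverage` (`H x W` tile counts, all >= 1).
#' @export
aggregate_predictions <- function(tile_maps, tileset) {
  stopifnot(inherits(tileset, "sg_tileset"))
  if (length(tile_maps) != nrow(tileset$offsets))
    stop("tile_maps does not align with the tileset offsets", call. = FALSE)
  ts <- tileset$tile_size
  nc <- dim(tile_maps[[1]])[3]
  Hp <- tileset$padded_height; Wp <- tileset$padded_width
  acc <- array(0, c(Hp, Wp, nc))
  cov <- matrix(0L, Hp, Wp)
  for (i in seq_along(tile_maps)) {
    m <- tile_maps[[i]]
    if (!all(dim(m)[1:2] == ts))
      stop("tile map ", i, " does not match the tile size", call. = FALSE)
    r <- tileset$offsets$row[i] + seq_len(ts)
    c <- tileset$offsets$col[i] + seq_len(ts)
    acc[r, c, ] <- acc[r, c, , drop = FALSE] + m
    cov[r, c] <- cov[r, c] + 1L
  }
  if (any(cov == 0L))
    stop("internal error: pixels with zero tile coverage", call. = FALSE)
  for (k in seq_len(nc)) acc[, , k] <- acc[, , k] / cov
  rows <- tileset$pad["top"] + seq_len(tileset$height)
  cols <- tileset$pad["left"] + seq_len(tileset$width)
  structure(list(weights = acc[rows, cols, , drop = FALSE],
                 coverage = cov[rows, cols, drop = FALSE]),
            class = "sg_soft")
}

#' Collapse a soft prediction to a class mask by per-pixel argmax
#'
#' Ties are broken toward the lowest class index (class coding starts at 0).
#'
#' @param soft an `sg_soft` object or a bare `H x W x n_class` array.
#' @return Integer `H x W` matrix of 0-based class labels.
#' @export
soft_to_mask <- function(soft) {
  w <- if (inherits(soft, "sg_soft")) soft$weights else soft
  if (anyNA(w) || any(!is.finite(w))) stop("non-finite class weights", call. = FALSE)
  H <- dim(w)[1]; W <- dim(w)[2]; nc <- dim(w)[3]
  flat <- matrix(w, H * W, nc)
  best <- max.col(flat, ties.method = "first") - 1L
  matrix(as.integer(best), H, W)
}

#' Intersection-over-union of one class between two masks
#'
#' `|A \mathrm{\cap} B| / |A \mathrm{\cup} B|` where A are the pixels of
#' `predicted` carrying `class_id` and B those of `reference`. When both
#' regions are empty the ratio is undefined and `NA` is returned.
#'
#' @param predicted,reference integer label matrices of identical size.
#' @param class_id class label (0-3).
#' @return IoU in `[0, 1]`, or `NA` when both regions are empty.
#' @export
compute_iou <- function(predicted, reference, class_id) {
  if (!all(dim(predicted) == dim(reference)))
    stop("mask dimensions differ", call. = FALSE)
  a <- predicted == class_id
  b <- reference == class_id
  uni <- sum(a | b)
  if (uni == 0L) return(NA_real_)
  sum(a & b) / uni
}

#' Per-class IoU report over a set of predicted/reference mask pairs
#'
#' Reports both the micro-averaged IoU (pixels pooled over all images before
#' forming the ratio) and the mean of per-image IoU values (images where the
#' class is absent from both masks are skipped in the mean).
#'
#' @param predicted,reference lists of label matrices, pairwise aligned.
#' @param classes integer class labels to report (default 0:3).
#' @return data.frame with columns `class`, `iou_micro`, `iou_mean_image`.
#' @export
iou_report <- function(predicted, reference, classes = 0:3) {
  stopifnot(length(predicted) == length(reference))
  rows <- lapply(classes, function(cl) {
    inter <- 0; uni <- 0; per <- c()
    for (i in seq_along(predicted)) {
      a <- predicted[[i]] == cl; b <- reference[[i]] == cl
      inter <- inter + sum(a & b)
      uni <- uni + sum(a | b)
      u <- sum(a | b)
      if (u > 0) per <- c(per, sum(a & b) / u)
    }
    data.frame(class = cl,
               iou_micro = if (uni > 0) inter / uni else NA_real_,
               iou_mean_image = if (length(per)) mean(per) else NA_real_)
  })
  do.call(rbind, rows)
}
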