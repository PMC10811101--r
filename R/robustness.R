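# Distortion robustness and magnification analysis.
#
# The experimental protocol distorts whole scenes (box blur with kernels
# including even sizes; multiplicative brightness change), then reruns the
# extraction + classification path and tabulates ACC / PR / AUC per
# distortion level against an undistorted baseline. Image magnification is
# proxied by the pixel area of the color-reference target and split at a
# fixed threshold.

#' Distortion sweep configuration
#'
#' @param blur_kernel_sizes box-blur kernel sides in px (default 3, 4, 5, 6).
#' @param brightness_deltas per-channel intensity changes in percent
#'   (default +20, +40, +60, -20, -40, -60).
#' @param magnification_threshold color-target area (px^2) separating large
#'   from small magnification (default 2.25e6, the full-resolution value;
#'   desk-scale data pass a proportionally smaller threshold).
#' @return Object of class `distortion_config`.
#' @export
distortion_config <- function(blur_kernel_sizes = c(3L, 4L, 5L, 6L),
                              brightness_deltas = c(20, 40, 60, -20, -40, -60),
                              magnification_threshold = 2.25e6) {
  if (any(blur_kernel_sizes < 1)) stop("kernel sizes must be >= 1", call. = FALSE)
  if (magnification_threshold <= 0) stop("threshold must be positive", call. = FALSE)
  structure(list(blur_kernel_sizes = as.integer(blur_kernel_sizes),
                 brightness_deltas = brightness_deltas,
                 magnification_threshold = magnification_threshold),
            class = "distortion_config")
}

# Normalized box sums along rows then columns with replicate padding.
# Anchor at floor(k/2): output(y) averages input rows y-a .. y-a+k-1.
box_filter_plane <- function(plane, k) {
  H <- nrow(plane); W <- ncol(plane)
  a <- k %/% 2L
  top <- a; bottom <- k - 1L - a
  P <- plane[c(rep(1L, top), seq_len(H), rep(H, bottom)), , drop = FALSE]
  cs <- rbind(0, apply(P, 2, cumsum))
  rows <- cs[(k + 1):(H + k), , drop = FALSE] - cs[1:H, , drop = FALSE]
  P2 <- rows[, c(rep(1L, top), seq_len(W), rep(W, bottom)), drop = FALSE]
  cs2 <- cbind(0, t(apply(P2, 1, cumsum)))
  (cs2[, (k + 1):(W + k), drop = FALSE] - cs2[, 1:W, drop = FALSE]) / (k * k)
}

#' Box blur with the kernel sizes of the distortion protocol
#'
#' Normalized k x k box filter applied channel-wise with replicate border
#' handling. Even kernel sizes are supported with the anchor at
#' `floor(k/2)` (the window extends one pixel further up/left than down/
#' right). Kernel 1 returns the image bit-identically.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param kernel_px kernel side (>= 1; must not exceed either image side).
#' @return Blurred integer image array.
#' @export
apply_blur <- function(image, kernel_px) {
  check_image(image)
  k <- as.integer(kernel_px)
  if (k < 1) stop("kernel must be >= 1", call. = FALSE)
  if (k == 1L) return(image)
  if (k > dim(image)[1] || k > dim(image)[2])
    stop("kernel larger than the image", call. = FALSE)
  out <- image
  for (ch in 1:3)
    out[, , ch] <- round_half_up(clamp255(box_filter_plane(image[, , ch], k)))
  array(as.integer(out), dim(image))
}

#' Multiplicative brightness change
#'
#' Every channel is scaled by `1 + delta_pct/100`, rounded half away from
#' zero and clipped to 0..255. `delta_pct = 0` is the identity.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param delta_pct percent change, greater than -100.
#' @return Adjusted integer image array.
#' @export
apply_brightness <- function(image, delta_pct) {
  check_image(image)
  if (delta_pct <= -100) stop("delta_pct must be > -100", call. = FALSE)
  if (delta_pct == 0) return(image)
  array(as.integer(round_half_up(clamp255(image * (1 + delta_pct / 100)))),
        dim(image))
}

#' Split image metadata by magnification proxy
#'
#' Magnification is large when the color-target area strictly exceeds the
#' threshold and small when it is at or below it; rows with a missing area
#' land in an `unknown` bucket.
#'
#' @param metadata data.frame with a `colorchecker_area` column.
#' @param threshold area threshold in px^2.
#' @return List of data.frames `large`, `small`, `unknown`.
#' @export
magnification_split <- function(metadata, threshold = 2.25e6) {
  area <- metadata$colorchecker_area
  if (is.null(area)) stop("metadata lacks a colorchecker_area column", call. = FALSE)
  list(large = metadata[!is.na(area) & area > threshold, , drop = FALSE],
       small = metadata[!is.na(area) & area <= threshold, , drop = FALSE],
       unknown = metadata[is.na(area), , drop = FALSE])
}

# Run the extraction + classification path on one (possibly distorted)
# scene; returns a score or NA when no crop survives.
score_one_scene <- function(image, mask, model, crop_cfg) {
  bb <- tryCatch(extract_bbox(mask), error = function(e) NULL)
  if (is.null(bb)) return(NA_real_)
  rect <- blackout_background(image, mask, bb)
  crops <- make_crops(rect$image, crop_cfg, rect$mask)
  if (length(crops) == 0L) return(NA_real_)
  predict_image(model, lapply(crops, `[[`, "image"))
}

#' Distortion sweep over a labelled scene set
#'
#' For each distortion level (plus an undistorted baseline) every scene is
#' distorted, segmented (with `segmenter`, or reusing the clean reference
#' masks when `use_reference_masks = TRUE`), reduced to crops and scored;
#' ACC, PR and AUC are tabulated per level. Scenes for which no crop
#' survives filtering are excluded and counted per row.
#'
#' @param model trained `sg_classifier`.
#' @param dataset [generate_dataset()]-layout list (scenes with masks and
#'   pubescence labels).
#' @param cfg a [distortion_config()].
#' @param crop_cfg a [crop_config()] for the extraction step.
#' @param segmenter model for [segment_scene()]; required unless
#'   `use_reference_masks = TRUE`.
#' @param tiling a [tiling_config()] for segmentation.
#' @param use_reference_masks reuse the clean ground-truth masks instead of
#'   re-segmenting the distorted scene.
#' @param threshold decision threshold for ACC/PR.
#' @return data.frame with columns `distortion_type` (`none`/`blur`/
#'   `brightness`), `level`, `n`, `n_excluded`, `ACC`, `PR`, `AUC`.
#' @export
distortion_sweep <- function(model, dataset, cfg = distortion_config(),
                             crop_cfg = crop_config(),
                             segmenter = NULL,
                             tiling = tiling_config(),
                             use_reference_masks = FALSE,
                             threshold = 0.5) {
  scenes <- dataset$scenes %||% dataset
  labels <- vapply(scenes, function(s) s$scene$pubescence, integer(1))
  if (!use_reference_masks && is.null(segmenter))
    stop("a segmenter is required unless use_reference_masks = TRUE", call. = FALSE)
  levels <- rbind(
    data.frame(distortion_type = "none", level = 0),
    if (length(cfg$blur_kernel_sizes))
      data.frame(distortion_type = "blur", level = cfg$blur_kernel_sizes),
    if (length(cfg$brightness_deltas))
      data.frame(distortion_type = "brightness", level = cfg$brightness_deltas)
  )
  rows <- lapply(seq_len(nrow(levels)), function(li) {
    ty <- levels$distortion_type[li]; lv <- levels$level[li]
    scores <- vapply(seq_along(scenes), function(i) {
      img <- scenes[[i]]$scene$image
      img <- switch(ty,
                    none = img,
                    blur = apply_blur(img, lv),
                    brightness = apply_brightness(img, lv))
      msk <- if (use_reference_masks) scenes[[i]]$mask
      else segment_scene(segmenter, img, tiling)
      score_one_scene(img, msk, model, crop_cfg)
    }, numeric(1))
    ok <- !is.na(scores)
    m <- if (any(ok))
      compute_metrics(scores = scores[ok], labels = labels[ok],
                      threshold = threshold)
    else list(ACC = NA_real_, PR = NA_real_, AUC = NA_real_)
    data.frame(distortion_type = ty, level = lv, n = sum(ok),
               n_excluded = sum(!ok), ACC = m$ACC, PR = m$PR, AUC = m$AUC)
  })
  do.call(rbind, rows)
}
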