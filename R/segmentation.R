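# 4-class scene segmentation.
#
# The segmenter is a compact fully convolutional network: two 3x3 conv + ReLU
# stages followed by a 1x1 conv to 4 class logits and a per-pixel softmax,
# trained with per-pixel cross-entropy and Adam. Being fully convolutional it
# accepts any tile size; inference runs over overlapping tiles (tile_image)
# and per-class weights are averaged per pixel (aggregate_predictions).

#' Segmentation training configuration
#'
#' The augmentation recipe applied to training tiles is: horizontal flip
#' (p = 0.5); a combined scale (factor drawn in 1 + `scale_limit`) and
#' rotation (angle within `rotate_limit` degrees) applied with probability
#' 0.75; brightness/contrast jitter (factors within 1 +/- 0.4) with
#' probability 0.75; followed by per-channel normalization. Validation and
#' test tiles are only normalized.
#'
#' @param encoder_name network backbone. This implementation provides the
#'   compact `"tiny"` encoder (alias `"tiny-test-encoder"`); other names are
#'   rejected.
#' @param n_filters feature channels of the two conv stages.
#' @param tiling a [tiling_config()] used to cut training tiles.
#' @param augment logical; apply the training augmentation recipe.
#' @param flip_p,scale_limit,rotate_limit,jitter_limit,aug_p augmentation
#'   parameters (see Details).
#' @param lr,epochs,batch_size,weight_decay Adam optimizer settings.
#' @param seed RNG seed; fixes initialization, shuffling and augmentation.
#' @return Object of class `seg_train_config`.
#' @export
seg_train_config <- function(encoder_name = "tiny", n_filters = 8L,
                             tiling = tiling_config(),
                             augment = TRUE,
                             flip_p = 0.5, scale_limit = c(0, 0.1),
                             rotate_limit = 5, jitter_limit = 0.4,
                             aug_p = 0.75,
                             lr = 1e-3, epochs = 10L, batch_size = 8L,
                             weight_decay = 0, seed = 1L) {
  if (!encoder_name %in% c("tiny", "tiny-test-encoder"))
    stop("unsupported encoder '", encoder_name,
         "': this implementation provides the compact 'tiny' encoder",
         call. = FALSE)
  stopifnot(epochs >= 1, lr > 0, flip_p >= 0, flip_p <= 1, aug_p >= 0, aug_p <= 1)
  structure(list(encoder_name = "tiny", n_filters = as.integer(n_filters),
                 tiling = tiling, augment = isTRUE(augment),
                 flip_p = flip_p, scale_limit = scale_limit,
                 rotate_limit = rotate_limit, jitter_limit = jitter_limit,
                 aug_p = aug_p, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "seg_train_config")
}

# Combined scale/rotation about the tile center; bilinear for the image,
# nearest for the mask, border pixels fall back to background (0).
affine_pair <- function(image, mask, scale, angle_deg) {
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(seq_len(H) - cy, H, W)
  cc <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  src_r <- (cos(th) * rr + sin(th) * cc) / scale + cy
  src_c <- (-sin(th) * rr + cos(th) * cc) / scale + cx
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  r0c <- pmin(pmax(r0, 1), H); r1c <- pmin(pmax(r0 + 1, 1), H)
  c0c <- pmin(pmax(c0, 1), W); c1c <- pmin(pmax(c0 + 1, 1), W)
  out <- image
  for (ch in seq_len(dim(image)[3])) {
    pl <- image[, , ch]
    out[, , ch] <-
      pl[cbind(c(r0c), c(c0c))] * (1 - fr) * (1 - fc) +
      pl[cbind(c(r1c), c(c0c))] * fr * (1 - fc) +
      pl[cbind(c(r0c), c(c1c))] * (1 - fr) * fc +
      pl[cbind(c(r1c), c(c1c))] * fr * fc
  }
  rn <- pmin(pmax(round(src_r), 1), H)
  cn <- pmin(pmax(round(src_c), 1), W)
  m_out <- matrix(mask[cbind(c(rn), c(cn))], H, W)
  outside <- src_r < 0.5 | src_r > H + 0.5 | src_c < 0.5 | src_c > W + 0.5
  m_out[outside] <- 0L
  for (ch in seq_len(dim(image)[3])) { pl <- out[, , ch]; pl[outside] <- 0; out[, , ch] <- pl }
  list(image = out, mask = m_out)
}

augment_tile_pair <- function(image, mask, cfg) {
  if (runif(1) < cfg$flip_p) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (runif(1) < cfg$aug_p) {
    s <- 1 + runif(1, cfg$scale_limit[1], cfg$scale_limit[2])
    ang <- runif(1, -cfg$rotate_limit, cfg$rotate_limit)
    ap <- affine_pair(image, mask, s, ang)
    image <- ap$image; mask <- ap$mask
  }
  if (runif(1) < cfg$aug_p) {
    fb <- 1 + runif(1, -cfg$jitter_limit, cfg$jitter_limit)
    fc <- 1 + runif(1, -cfg$jitter_limit, cfg$jitter_limit)
    image <- image * fb
    m <- mean(image)
    image <- clamp255((image - m) * fc + m)
  }
  list(image = image, mask = mask)
}

seg_init_params <- function(n_filters) {
  F <- n_filters
  list(W1 = init_w(27L, F), b1 = numeric(F),
       W2 = init_w(9L * F, F), b2 = numeric(F),
       W3 = init_w(F, 4L), b3 = numeric(4L))
}

# Forward pass on a normalized H x W x 3 array. Returns per-pixel class
# probabilities (rows = pixels, column-major) plus caches for backprop.
seg_forward <- function(params, xn) {
  H <- dim(xn)[1]; W <- dim(xn)[2]
  F <- length(params$b1)
  X1 <- im2col3(xn)
  A1 <- X1 %*% params$W1
  A1 <- sweep(A1, 2, params$b1, "+")
  A1[A1 < 0] <- 0
  X2 <- im2col3(array(A1, c(H, W, F)))
  A2 <- X2 %*% params$W2
  A2 <- sweep(A2, 2, params$b2, "+")
  A2[A2 < 0] <- 0
  logits <- sweep(A2 %*% params$W3, 2, params$b3, "+")
  probs <- softmax_rows(logits)
  list(probs = probs, X1 = X1, A1 = A1, X2 = X2, A2 = A2, H = H, W = W)
}

# Cross-entropy gradient for one tile; labels is an H x W class matrix.
seg_backward <- function(params, fw, labels) {
  n <- fw$H * fw$W
  F <- length(params$b1)
  y <- as.integer(labels) + 1L
  dlog <- fw$probs
  dlog[cbind(seq_len(n), y)] <- dlog[cbind(seq_len(n), y)] - 1
  dlog <- dlog / n
  dW3 <- crossprod(fw$A2, dlog)
  db3 <- colSums(dlog)
  dA2 <- dlog %*% t(params$W3)
  dA2[fw$A2 <= 0] <- 0
  dW2 <- crossprod(fw$X2, dA2)
  db2 <- colSums(dA2)
  dX2 <- dA2 %*% t(params$W2)
  dA1arr <- col2im3(dX2, fw$H, fw$W, F)
  dA1 <- matrix(dA1arr, n, F)
  dA1[fw$A1 <= 0] <- 0
  dW1 <- crossprod(fw$X1, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

seg_tile_loss <- function(probs, labels) {
  y <- as.integer(labels) + 1L
  p <- probs[cbind(seq_along(y), y)]
  -mean(log(pmax(p, 1e-12)))
}

# Accept (image, mask) pairs in either the generate_dataset() layout or a
# plain list of list(image=, mask=).
as_seg_pairs <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$scenes)) dataset <- dataset$scenes
  lapply(dataset, function(d) {
    if (!is.null(d$scene)) list(image = d$scene$image, mask = d$mask)
    else list(image = d$image, mask = d$mask)
  })
}

#' Train the compact 4-class segmenter
#'
#' Scenes are cut into tiles with the configured tiling; training tiles are
#' augmented per the config recipe and normalized; optimization is per-pixel
#' cross-entropy with Adam. The run is deterministic given `cfg$seed`.
#'
#' @param dataset a [generate_dataset()] result or a list of
#'   `list(image =, mask =)` pairs.
#' @param cfg a [seg_train_config()].
#' @return Object of class `sg_segmenter`: network parameters, the config,
#'   normalization constants, the class map and a per-epoch loss log
#'   (`model$log`, data.frame epoch/loss).
#' @export
train_segmenter <- function(dataset, cfg = seg_train_config()) {
  pairs <- as_seg_pairs(dataset)
  if (length(pairs) == 0) stop("empty training dataset", call. = FALSE)
  set.seed(cfg$seed)
  tiles <- list()
  for (p in pairs) {
    ti <- tile_image(p$image, cfg$tiling)
    tm <- tile_image(p$mask, cfg$tiling)
    for (j in seq_along(ti$tiles))
      tiles[[length(tiles) + 1L]] <- list(image = ti$tiles[[j]],
                                          mask = tm$tiles[[j]])
  }
  present <- sort(unique(unlist(lapply(tiles, function(t) unique(as.integer(t$mask))))))
  missing_cls <- setdiff(0:3, present)
  if (length(missing_cls))
    warning("classes absent from all training masks: ",
            paste(missing_cls, collapse = ", "), call. = FALSE)

  params <- seg_init_params(cfg$n_filters)
  state <- adam_init(params)
  log <- data.frame(epoch = integer(), loss = numeric())
  n <- length(tiles)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    done <- 0L
    while (done < n) {
      idx <- ord[(done + 1L):min(done + cfg$batch_size, n)]
      grads <- NULL
      for (i in idx) {
        t <- tiles[[i]]
        img <- t$image; msk <- t$mask
        if (cfg$augment) {
          a <- augment_tile_pair(img, msk, cfg)
          img <- a$image; msk <- a$mask
        }
        fw <- seg_forward(params, normalize_image(img))
        ep_loss <- ep_loss + seg_tile_loss(fw$probs, msk)
        g <- seg_backward(params, fw, msk)
        grads <- if (is.null(grads)) g
        else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- adam_step(params, grads, state, cfg$lr,
                       weight_decay = cfg$weight_decay)
      params <- upd$params; state <- upd$state
      done <- done + length(idx)
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n))
  }
  structure(list(type = "segmenter", encoder_name = cfg$encoder_name,
                 params = params, cfg = cfg,
                 norm_mean = NORM_MEAN, norm_sd = NORM_SD,
                 classes = MASK_CLASSES, log = log),
            class = "sg_segmenter")
}

#' Per-pixel soft class prediction for one image or tile
#'
#' Generic over model types: the trained compact segmenter, or a pointwise
#' stub model built with [pointwise_model()].
#'
#' @param model a model object.
#' @param image `H x W x 3` array in 0..255.
#' @return `H x W x n_class` array of class weights in `[0, 1]`.
#' @export
predict_soft <- function(model, image) UseMethod("predict_soft")

#' @export
predict_soft.sg_segmenter <- function(model, image) {
  fw <- seg_forward(model$params, normalize_image(image))
  array(fw$probs, c(fw$H, fw$W, 4L))
}

#' @export
predict_soft.sg_pointwise_model <- function(model, image) model$fn(image)

#' Wrap a pixel-wise function as a (translation-invariant) stub model
#'
#' The function receives the `H x W x 3` image and must return an
#' `H x W x n_class` weight array computed independently per pixel. Useful
#' as a deterministic oracle for the tiled-inference machinery.
#'
#' @param fn the pixel-wise prediction function.
#' @return Object of class `sg_pointwise_model`.
#' @export
pointwise_model <- function(fn) {
  structure(list(fn = fn), class = "sg_pointwise_model")
}

#' Predict soft maps for every tile of a tileset
#'
#' @param model model accepted by [predict_soft()].
#' @param tileset an [tile_image()] result.
#' @return List of `tile_size x tile_size x n_class` arrays, aligned with
#'   `tileset$offsets`.
#' @export
predict_tiles <- function(model, tileset) {
  stopifnot(inherits(tileset, "sg_tileset"))
  lapply(tileset$tiles, function(t) {
    m <- predict_soft(model, t)
    if (!all(dim(m)[1:2] == dim(t)[1:2]))
      stop("model output size does not match the tile size", call. = FALSE)
    m
  })
}

#' Segment a whole scene by tiled, overlap-averaged inference
#'
#' @param model model accepted by [predict_soft()].
#' @param image `H x W x 3` array.
#' @param tiling a [tiling_config()].
#' @return `segment_scene_soft()` returns the `sg_soft` prediction;
#'   `segment_scene()` the argmax class mask.
#' @export
segment_scene_soft <- function(model, image, tiling = tiling_config()) {
  ts <- tile_image(image, tiling)
  aggregate_predictions(predict_tiles(model, ts), ts)
}

#' @rdname segment_scene_soft
#' @export
segment_scene <- function(model, image, tiling = tiling_config()) {
  soft_to_mask(segment_scene_soft(model, image, tiling))
}

#' Save / load a model artifact
#'
#' Writes the weights as `weights.rds` plus a JSON sidecar
#' (`model.json`: model type, encoder, normalization constants, class map,
#' seed) into `dir`.
#'
#' @param model an `sg_segmenter` or `sg_classifier`.
#' @param dir artifact directory.
#' @return `save_model()` the directory, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "weights.rds"))
  sidecar <- list(type = model$type,
                  encoder = model$encoder_name %||% model$backbone,
                  norm_mean = model$norm_mean, norm_sd = model$norm_sd,
                  classes = as.list(model$classes),
                  seed = model$cfg$seed)
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) readRDS(file.path(dir, "weights.rds"))

`%||%` <- function(a, b) if (is.null(a)) b else a
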