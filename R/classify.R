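# Binary glume-pubescence classification of spike-body crops.
#
# The compact classifier is conv(3x3, 3->F) + ReLU + 2x2 mean pool +
# conv(3x3, F->F) + ReLU + dual global pooling (per-channel mean and max,
# the max path keeping the sparse hair-texture response from being diluted
# by the large smooth body interior) + linear head + sigmoid, trained with
# binary cross-entropy and Adam. Pubescent (haired) is the
# positive class (label 1) everywhere. Grad-CAM maps are computed from the
# analytic gradient of the pre-sigmoid score with respect to the last
# convolutional feature maps.

#' Classifier training configuration
#'
#' Defaults mirror a fine-tuning regime on full-scale photographs
#' (lr = 1e-7, weight decay = 1e-6, 150 epochs, batch 16); desk-scale runs
#' on randomly initialized compact networks override `lr` and `epochs`.
#'
#' @param backbone `"tiny"` (alias `"tiny-test-cnn"`), the compact CNN
#'   provided by this implementation; other names are rejected.
#' @param input_size square network input side in px; crops of any other
#'   size are resampled bilinearly.
#' @param n_filters feature channels of the conv stages.
#' @param lr,weight_decay,epochs,batch_size Adam settings.
#' @param brightness,contrast,saturation training-time jitter half-ranges
#'   (multiplicative factors drawn in 1 +/- range).
#' @param aug_p probability of applying the jitter to a training crop.
#' @param pretrained must be `FALSE`: no pretrained weights ship with the
#'   compact backbone.
#' @param threshold decision threshold on the pubescence score
#'   (score >= threshold predicts pubescent).
#' @param checkpoint `"best_val_auc"` keeps the epoch with the best
#'   validation AUC when a validation set is supplied; `"last"` keeps the
#'   final epoch.
#' @param seed RNG seed.
#' @return Object of class `cls_train_config`.
#' @export
cls_train_config <- function(backbone = "tiny", input_size = 64L,
                             n_filters = 8L,
                             lr = 1e-7, weight_decay = 1e-6,
                             epochs = 150L, batch_size = 16L,
                             brightness = 0.4, contrast = 0.4,
                             saturation = 0.2, aug_p = 0.75,
                             pretrained = FALSE,
                             threshold = 0.5,
                             checkpoint = c("best_val_auc", "last"),
                             seed = 1L) {
  if (!backbone %in% c("tiny", "tiny-test-cnn"))
    stop("unsupported backbone '", backbone,
         "': this implementation provides the compact 'tiny' CNN", call. = FALSE)
  if (isTRUE(pretrained))
    stop("no pretrained weights are available for the compact backbone",
         call. = FALSE)
  stopifnot(lr > 0, epochs >= 1, input_size %% 4L == 0L)
  structure(list(backbone = "tiny", input_size = as.integer(input_size),
                 n_filters = as.integer(n_filters), lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, aug_p = aug_p,
                 pretrained = FALSE, threshold = threshold,
                 checkpoint = match.arg(checkpoint),
                 seed = as.integer(seed)),
            class = "cls_train_config")
}

cls_init_params <- function(n_filters) {
  F <- n_filters
  list(W1 = init_w(27L, F), b1 = numeric(F),
       W2 = init_w(9L * F, F), b2 = numeric(F),
       w_mean = matrix(rnorm(F, 0, sqrt(1 / F)), F, 1),
       w_max = matrix(rnorm(F, 0, sqrt(1 / F)), F, 1), b = 0)
}

cls_prepare <- function(crop, input_size) {
  d <- dim(crop)
  if (d[1] != input_size || d[2] != input_size)
    crop <- resize_image(crop, input_size, input_size)
  normalize_image(crop)
}

cls_forward <- function(params, xn) {
  s <- dim(xn)[1]
  F <- length(params$b1)
  X1 <- im2col3(xn)
  A1 <- sweep(X1 %*% params$W1, 2, params$b1, "+")
  A1[A1 < 0] <- 0
  P <- meanpool2(array(A1, c(s, s, F)))
  sp <- s %/% 2L
  X2 <- im2col3(P)
  A2 <- sweep(X2 %*% params$W2, 2, params$b2, "+")
  A2[A2 < 0] <- 0
  g_mean <- colMeans(A2)
  imax <- max.col(t(A2), ties.method = "first")
  g_max <- A2[cbind(imax, seq_len(F))]
  z <- sum(params$w_mean * g_mean) + sum(params$w_max * g_max) + params$b
  list(score = stats::plogis(z), z = z, g_mean = g_mean, g_max = g_max,
       imax = imax, X1 = X1, A1 = A1, X2 = X2, A2 = A2, s = s, sp = sp)
}

cls_backward <- function(params, fw, y) {
  F <- length(params$b1)
  npix2 <- fw$sp^2
  dz <- fw$score - y
  dw_mean <- matrix(dz * fw$g_mean, F, 1)
  dw_max <- matrix(dz * fw$g_max, F, 1)
  db <- dz
  dg_mean <- dz * as.numeric(params$w_mean)
  dA2 <- matrix(rep(dg_mean, each = npix2) / npix2, npix2, F)
  dA2[cbind(fw$imax, seq_len(F))] <- dA2[cbind(fw$imax, seq_len(F))] +
    dz * as.numeric(params$w_max)
  dA2[fw$A2 <= 0] <- 0
  dW2 <- crossprod(fw$X2, dA2)
  db2 <- colSums(dA2)
  dX2 <- dA2 %*% t(params$W2)
  dP <- col2im3(dX2, fw$sp, fw$sp, F)
  dA1arr <- meanpool2_back(dP, fw$s, fw$s)
  dA1 <- matrix(dA1arr, fw$s^2, F)
  dA1[fw$A1 <= 0] <- 0
  dW1 <- crossprod(fw$X1, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       w_mean = dw_mean, w_max = dw_max, b = db)
}

jitter_crop <- function(crop, cfg) {
  x <- crop
  fb <- 1 + runif(1, -cfg$brightness, cfg$brightness)
  x <- x * fb
  m <- mean(x)
  fc <- 1 + runif(1, -cfg$contrast, cfg$contrast)
  x <- (x - m) * fc + m
  fs <- 1 + runif(1, -cfg$saturation, cfg$saturation)
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  for (ch in 1:3) x[, , ch] <- gray + (x[, , ch] - gray) * fs
  clamp255(x)
}

#' Train the binary pubescence classifier
#'
#' @param crops list of spike-body crop arrays (any square size; resampled
#'   to `cfg$input_size`).
#' @param labels binary vector (1 = pubescent) aligned with `crops`.
#' @param cfg a [cls_train_config()].
#' @param val_crops,val_labels optional validation set used for per-epoch
#'   AUC logging and `"best_val_auc"` checkpoint selection.
#' @return Object of class `sg_classifier` with parameters, config,
#'   normalization constants and a per-epoch log (`$log`: epoch, loss, and
#'   `val_auc` when validation data were supplied).
#' @export
train_classifier <- function(crops, labels, cfg = cls_train_config(),
                             val_crops = NULL, val_labels = NULL) {
  stopifnot(length(crops) == length(labels))
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary (1 = pubescent)", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("single-class training set: need both classes", call. = FALSE)
  if (min(table(labels)) < 2L)
    warning("fewer than 2 examples in one class", call. = FALSE)
  set.seed(cfg$seed)
  prepared <- lapply(crops, cls_prepare, input_size = cfg$input_size)
  # raw crops kept for jitter (jitter acts on intensities, then normalize)
  raw <- lapply(crops, function(cr) {
    d <- dim(cr)
    if (d[1] != cfg$input_size || d[2] != cfg$input_size)
      resize_image(cr, cfg$input_size, cfg$input_size) else cr
  })
  params <- cls_init_params(cfg$n_filters)
  state <- adam_init(params)
  n <- length(crops)
  log <- NULL
  best <- list(auc = -Inf, params = params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    done <- 0L
    while (done < n) {
      idx <- ord[(done + 1L):min(done + cfg$batch_size, n)]
      grads <- NULL
      for (i in idx) {
        xn <- if (runif(1) < cfg$aug_p)
          normalize_image(jitter_crop(raw[[i]], cfg)) else prepared[[i]]
        fw <- cls_forward(params, xn)
        p <- min(max(fw$score, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - (labels[i] * log(p) + (1 - labels[i]) * log(1 - p))
        g <- cls_backward(params, fw, labels[i])
        grads <- if (is.null(grads)) g else Map(`+`, grads, g)
      }
      grads <- lapply(grads, function(g) g / length(idx))
      upd <- adam_step(params, grads, state, cfg$lr,
                       weight_decay = cfg$weight_decay)
      params <- upd$params; state <- upd$state
      done <- done + length(idx)
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n)
    if (!is.null(val_crops)) {
      model_ep <- new_classifier(params, cfg)
      vs <- vapply(val_crops, function(cr) cls_score(model_ep, cr), numeric(1))
      va <- auc_score(vs, val_labels)
      row$val_auc <- va
      if (!is.na(va) && va > best$auc)
        best <- list(auc = va, params = params, epoch = ep)
    }
    log <- rbind(log, row)
  }
  final_params <- if (cfg$checkpoint == "best_val_auc" && !is.null(val_crops) &&
                      best$epoch > 0L) best$params else params
  model <- new_classifier(final_params, cfg)
  model$log <- log
  model$checkpoint_epoch <- if (cfg$checkpoint == "best_val_auc" &&
                                !is.null(val_crops)) best$epoch else cfg$epochs
  model
}

new_classifier <- function(params, cfg) {
  structure(list(type = "classifier", backbone = cfg$backbone,
                 params = params, cfg = cfg,
                 norm_mean = NORM_MEAN, norm_sd = NORM_SD,
                 classes = c(glabrous = 0L, pubescent = 1L)),
            class = "sg_classifier")
}

#' Pubescence score of a single crop
#'
#' @param model an `sg_classifier`.
#' @param crop crop array.
#' @return Score in `[0, 1]`; larger means more pubescent-like.
#' @export
cls_score <- function(model, crop) {
  cls_forward(model$params, cls_prepare(crop, model$cfg$input_size))$score
}

#' Image-level pubescence score from one or more crops
#'
#' A single (medium/large/resized) crop yields its own score; multiple
#' (small) crops are aggregated by the arithmetic mean of their scores.
#'
#' @param model an `sg_classifier`.
#' @param crops non-empty list of crop arrays (or a single array).
#' @param aggregation `"mean"`.
#' @return Score in `[0, 1]`.
#' @export
predict_image <- function(model, crops, aggregation = "mean") {
  if (is.array(crops)) crops <- list(crops)
  if (length(crops) == 0L)
    stop("no crops available for this image (no-prediction)", call. = FALSE)
  scores <- vapply(crops, function(cr) cls_score(model, cr), numeric(1))
  switch(aggregation,
         mean = mean(scores),
         stop("unknown aggregation '", aggregation, "'", call. = FALSE))
}

#' Confusion counts at a decision threshold
#'
#' Scores at or above the threshold predict the positive (pubescent) class.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels binary reference labels (1 = pubescent).
#' @param threshold decision threshold (default 0.5).
#' @return Object of class `sg_confusion`: list(TP, TN, FP, FN, P, N).
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  structure(list(
    TP = sum(pred == 1L & labels == 1L),
    TN = sum(pred == 0L & labels == 0L),
    FP = sum(pred == 1L & labels == 0L),
    FN = sum(pred == 0L & labels == 1L),
    P = sum(labels == 1L), N = sum(labels == 0L)
  ), class = "sg_confusion")
}

# Rank (Mann-Whitney) AUC; tied score pairs count 1/2.
auc_score <- function(scores, labels) {
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Classification performance metrics
#'
#' ACC = (TP + TN) / (P + N); precision PR = TP / (TP + FP);
#' F1 = 2 TP / (2 TP + FP + FN); AUC by the rank (Mann-Whitney)
#' formulation with ties counted 1/2. PR is `NA` when no positive
#' prediction was made, F1 when TP + FP + FN = 0, and AUC when either class
#' is absent.
#'
#' @param cc an [confusion_counts()] result (or `NULL` to derive it from
#'   `scores`/`labels` at `threshold`).
#' @param scores,labels score/label vectors for the AUC (optional if only
#'   threshold metrics are needed).
#' @param threshold used when `cc` is `NULL`.
#' @return Object of class `sg_metrics`: list(ACC, PR, F1, AUC).
#' @export
compute_metrics <- function(cc = NULL, scores = NULL, labels = NULL,
                            threshold = 0.5) {
  if (is.null(cc)) cc <- confusion_counts(scores, labels, threshold)
  acc <- (cc$TP + cc$TN) / (cc$P + cc$N)
  pr <- if (cc$TP + cc$FP > 0) cc$TP / (cc$TP + cc$FP) else NA_real_
  f1 <- if (2 * cc$TP + cc$FP + cc$FN > 0)
    2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN) else NA_real_
  auc <- if (!is.null(scores)) auc_score(scores, labels) else NA_real_
  structure(list(ACC = acc, PR = pr, F1 = f1, AUC = auc), class = "sg_metrics")
}

#' Grad-CAM activation map for one crop
#'
#' The gradient of the pre-sigmoid pubescence score with respect to the last
#' convolutional feature maps is averaged spatially into per-channel
#' weights; the weighted sum of the feature maps is rectified, bilinearly
#' upsampled to the crop size and min-max normalized. When the gradient
#' signal is identically zero an all-zero map is returned with attribute
#' `all_zero = TRUE`.
#'
#' @param model an `sg_classifier`.
#' @param crop crop array (`H x W x 3`).
#' @return `H x W` matrix in `[0, 1]` (attribute `all_zero` flags a
#'   degenerate map).
#' @export
activation_map <- function(model, crop) {
  H <- dim(crop)[1]; W <- dim(crop)[2]
  fw <- cls_forward(model$params, cls_prepare(crop, model$cfg$input_size))
  npix2 <- fw$sp^2
  # spatial mean of d z / d A2: the mean-pool path contributes w_mean_k /
  # npix2 everywhere, the max-pool path w_max_k at the argmax location only
  alpha <- as.numeric(model$params$w_mean + model$params$w_max) / npix2
  cam <- matrix(fw$A2 %*% matrix(alpha, ncol = 1), fw$sp, fw$sp)
  cam[cam < 0] <- 0
  if (max(cam) == 0 || all(alpha == 0)) {
    out <- matrix(0, H, W)
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  eb <- EBImage::resize(EBImage::Image(t(cam)), w = W, h = H,
                        filter = "bilinear")
  up <- t(EBImage::imageData(eb))
  up[up < 0] <- 0
  out <- (up - min(up)) / (max(up) - min(up))
  attr(out, "all_zero") <- FALSE
  out
}
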