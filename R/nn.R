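# Minimal convolutional network machinery.
#
# The compact segmenter and classifier used in this package are built from
# 3x3 same-padding convolutions expressed as im2col + matrix products, ReLU,
# 2x2 mean pooling, global average pooling and a linear head, trained with
# Adam. Everything is plain R linear algebra, so a fixed RNG seed gives
# bit-reproducible training runs.
#
# Layout conventions: feature maps are H x W x C arrays; an im2col matrix
# has one row per pixel (column-major pixel order) and one column per
# (channel, kernel-offset) pair; a conv weight matrix is (9*Cin) x Cout with
# the same column ordering.

im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 0L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    cols[, k] <- xp[(1L + dy):(H + dy), (1L + dx):(W + dx), ci]
  }
  cols
}

# Adjoint of im2col3: scatter-add the columns back onto an H x W x C array.
col2im3 <- function(cols, H, W, C) {
  xp <- array(0, c(H + 2L, W + 2L, C))
  k <- 0L
  for (ci in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    xp[(1L + dy):(H + dy), (1L + dx):(W + dx), ci] <-
      xp[(1L + dy):(H + dy), (1L + dx):(W + dx), ci] + matrix(cols[, k], H, W)
  }
  xp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

meanpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  (x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
   x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
   x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
   x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
}

meanpool2_back <- function(dp, H, W) {
  C <- dim(dp)[3]
  dx <- array(0, c(H, W, C))
  q <- dp / 4
  dx[seq(1, H, 2), seq(1, W, 2), ] <- q
  dx[seq(2, H, 2), seq(1, W, 2), ] <- q
  dx[seq(1, H, 2), seq(2, W, 2), ] <- q
  dx[seq(2, H, 2), seq(2, W, 2), ] <- q
  dx
}

# He-style initialization for a (fan_in x fan_out) weight matrix.
init_w <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Row-wise softmax with the usual max-shift for stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
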