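test_that("tile offsets follow the stride grid with border clamping", {
  ts <- tile_image(array(0, c(512, 512, 3)))
  expect_equal(nrow(ts$offsets), 1)
  expect_equal(unlist(ts$offsets[1, ]), c(row = 0, col = 0))
  # 768 x 1024 scene: rows {0, 256}, cols {0, 256, 512}
  ts2 <- tile_image(array(0, c(768, 1024, 3)))
  expect_equal(sort(unique(ts2$offsets$row)), c(0, 256))
  expect_equal(sort(unique(ts2$offsets$col)), c(0, 256, 512))
  expect_equal(nrow(ts2$offsets), 6)
  # 700 x 512: the 256 offset clamps to 700 - 512 = 188
  ts3 <- tile_image(array(0, c(700, 512, 3)))
  expect_equal(sort(unique(ts3$offsets$row)), c(0, 188))
  expect_equal(nrow(ts3$offsets), 2)
  expect_error(tiling_config(512, 0))
  expect_error(tiling_config(256, 512))
})

test_that("small images are padded symmetrically and cropped back", {
  img <- array(runif(100 * 80 * 3, 0, 255), c(100, 80, 3))
  ts <- tile_image(img)
  expect_equal(nrow(ts$offsets), 1)
  expect_equal(dim(ts$tiles[[1]]), c(512, 512, 3))
  stub <- pointwise_model(function(x) {
    w <- array(0, c(dim(x)[1:2], 4))
    w[, , 1] <- x[, , 1] / 255
    w[, , 2] <- 1 - x[, , 1] / 255
    w
  })
  soft <- aggregate_predictions(predict_tiles(stub, ts), ts)
  expect_equal(dim(soft$weights), c(100, 80, 4))
  expect_true(all(soft$coverage >= 1))
})

test_that("per-pixel weights are averaged over covering tiles", {
  # two overlapping tiles with constant class-2 weights 0.6 and 0.8
  ts <- tile_image(array(0, c(512, 768, 3)))
  expect_equal(nrow(ts$offsets), 2)
  maps <- list(array(rep(c(0.4, 0, 0.6, 0), each = 512 * 512), c(512, 512, 4)),
               array(rep(c(0.2, 0, 0.8, 0), each = 512 * 512), c(512, 512, 4)))
  soft <- aggregate_predictions(maps, ts)
  overlap_col <- 300   # covered by both tiles (offsets 0 and 256)
  expect_equal(soft$weights[10, overlap_col, 3], 0.7)
  expect_equal(soft$coverage[10, overlap_col], 2L)
  expect_equal(soft$weights[10, 10, 3], 0.6)   # first tile only
  expect_equal(soft$weights[10, 700, 3], 0.8)  # second tile only
})

test_that("interior coverage is 4 under default tiling of a large scene", {
  ts <- tile_image(array(0, c(1024, 1024, 3)))
  cmaps <- lapply(seq_len(nrow(ts$offsets)),
                  function(i) array(0.25, c(512, 512, 4)))
  soft <- aggregate_predictions(cmaps, ts)
  expect_equal(soft$coverage[512, 512], 4L)
  expect_true(all(soft$coverage >= 1))
  # constant model stays constant after aggregation
  expect_true(all(soft$weights == 0.25))
})

test_that("argmax conversion matches a brute-force scan and breaks ties low", {
  expect_equal(soft_to_mask(array(c(0.1, 0.2, 0.6, 0.1), c(1, 1, 4)))[1, 1], 2L)
  expect_equal(soft_to_mask(array(0.25, c(1, 1, 4)))[1, 1], 0L)
  set.seed(44)
  w <- array(runif(20 * 15 * 4), c(20, 15, 4))
  w[3, 4, ] <- c(0.5, 0.5, 0.2, 0.1)      # deliberate tie
  got <- soft_to_mask(w)
  ref <- matrix(0L, 20, 15)
  for (i in 1:20) for (j in 1:15) {
    v <- w[i, j, ]
    ref[i, j] <- (which(v == max(v))[1]) - 1L
  }
  expect_identical(got, ref)
})

test_that("IoU matches set arithmetic and flags the empty-empty case", {
  m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 2L
  expect_equal(compute_iou(m, m, 2L), 1)
  n <- matrix(0L, 8, 8); n[6:8, 6:8] <- 2L
  expect_equal(compute_iou(m, n, 2L), 0)
  a <- matrix(0L, 4, 4); a[1, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[1, 3:4] <- 1L; b[2, 1:2] <- 1L
  expect_equal(compute_iou(a, b, 1L), 2 / 6)
  expect_true(is.na(compute_iou(a, b, 3L)))
  expect_error(compute_iou(a, matrix(0L, 5, 4), 1L), "dimensions")
  # symmetry and range over random masks
  set.seed(99)
  for (i in 1:20) {
    p <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    q <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    for (cl in 0:3) {
      v <- compute_iou(p, q, cl)
      expect_equal(v, compute_iou(q, p, cl))
      if (!is.na(v)) expect_true(v >= 0 && v <= 1)
    }
  }
})

test_that("tiled inference reproduces whole-image application of a pointwise model", {
  # denominators chosen coprime so no two class weights can tie exactly
  stub <- pointwise_model(function(x) {
    w <- array(0, c(dim(x)[1:2], 4))
    w[, , 1] <- 0.2
    w[, , 2] <- x[, , 2] / 257
    w[, , 3] <- x[, , 1] / 509
    w[, , 4] <- 1 - x[, , 3] / 263
    w
  })
  set.seed(5)
  img <- array(sample(0:255, 600 * 530 * 3, replace = TRUE), c(600, 530, 3))
  direct <- soft_to_mask(stub$fn(img))
  tiled <- segment_scene(stub, img)
  expect_identical(tiled, direct)
  softs <- segment_scene_soft(stub, img)
  expect_equal(softs$weights, stub$fn(img), tolerance = 1e-12)
})

test_that("iou_report labels micro and mean-per-image averages", {
  p1 <- matrix(0L, 4, 4); p1[1:2, 1:2] <- 2L
  r1 <- matrix(0L, 4, 4); r1[1:2, 1:2] <- 2L
  p2 <- matrix(0L, 4, 4); p2[1, 1] <- 2L
  r2 <- matrix(0L, 4, 4); r2[1, 1:2] <- 2L
  rep <- iou_report(list(p1, p2), list(r1, r2), classes = 2L)
  expect_equal(rep$iou_micro, (4 + 1) / (4 + 2))
  expect_equal(rep$iou_mean_image, mean(c(1, 0.5)))
})
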