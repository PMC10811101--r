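test_that("bounding boxes are tight half-open hulls of the body class", {
  m <- matrix(0L, 30, 30)
  m[11:21, 6:9] <- 2L     # rows 10-20, cols 5-8 in 0-based terms
  bb <- extract_bbox(m)
  expect_equal(unlist(bb[c("row_min", "col_min", "row_max", "col_max")]),
               c(row_min = 11, col_min = 6, row_max = 22, col_max = 10))
  full <- matrix(2L, 7, 9)
  bbf <- extract_bbox(full)
  expect_equal(c(bbf$row_max - bbf$row_min, bbf$col_max - bbf$col_min), c(7, 9))
  expect_error(extract_bbox(matrix(0L, 5, 5)), "empty-spike")
  # random masks against a brute-force hull scan
  set.seed(12)
  for (i in 1:25) {
    r <- matrix(sample(c(0L, 2L, 3L), 100, replace = TRUE, prob = c(.7, .2, .1)),
                10, 10)
    if (!any(r == 2L)) next
    bb <- extract_bbox(r)
    idx <- which(r == 2L, arr.ind = TRUE)
    expect_equal(bb$row_min, min(idx[, 1]))
    expect_equal(bb$row_max, max(idx[, 1]) + 1L)
    expect_equal(bb$col_min, min(idx[, 2]))
    expect_equal(bb$col_max, max(idx[, 2]) + 1L)
  }
})

test_that("blackout keeps only spike-body pixels and is idempotent", {
  set.seed(3)
  img <- array(sample(10:255, 40 * 30 * 3, replace = TRUE), c(40, 30, 3))
  msk <- matrix(0L, 40, 30)
  msk[10:30, 8:20] <- 2L
  msk[12, 10] <- 3L            # awn pixel inside the box
  msk[15, 12] <- 1L            # target pixel inside the box
  bb <- extract_bbox(msk)
  out <- blackout_background(img, msk, bb)
  expect_equal(out$image[3, 3, ], c(0, 0, 0))          # awn at (12,10) -> box (3,3)
  expect_equal(out$image[6, 5, ], c(0, 0, 0))          # target pixel
  expect_equal(out$image[1, 1, ], img[10, 8, ])        # body pixel unchanged
  nonblack <- sum(apply(out$image, c(1, 2), function(v) any(v > 0)))
  expect_equal(nonblack, sum(msk[10:30, 8:20] == 2L))
  # idempotence
  again <- blackout_background(out$image, out$mask)
  expect_identical(again$image, out$image)
})

test_that("central crops are centered and pad outside the rectangle with black", {
  set.seed(8)
  rect <- array(sample(50:255, 60 * 30 * 3, replace = TRUE), c(60, 30, 3))
  mrect <- matrix(2L, 60, 30)
  cfg <- crop_config("large_central", large = 86L)
  cr <- make_crops(rect, cfg, mrect)[[1]]
  expect_equal(dim(cr$image), c(86, 86, 3))
  # columns beyond the 30-wide rectangle are black, interior preserved
  expect_true(all(cr$image[, 75:86, ] == 0))
  expect_true(all(cr$image[, 1:10, ] == 0))
  ctr <- floor((1 + 60) / 2)
  expect_equal(cr$offset_row, ctr - (86L - 1L) %/% 2L)
  # exact-size medium crop equals the rectangle
  rect2 <- array(sample(50:255, 52 * 52 * 3, replace = TRUE), c(52, 52, 3))
  cr2 <- make_crops(rect2, crop_config("medium_central", medium = 52L),
                    matrix(2L, 52, 52))[[1]]
  expect_identical(cr2$image, rect2 * 1.0)
  # crop center coincides with the rectangle center within 1 px
  ctr_out_row <- cr$offset_row + 86 %/% 2
  expect_lte(abs(ctr_out_row - ctr), 1)
})

test_that("random small crops are seeded and bounded by rectangle size", {
  set.seed(1)
  rect <- array(sample(50:255, 64 * 48 * 3, replace = TRUE), c(64, 48, 3))
  mrect <- matrix(2L, 64, 48)
  cfg <- crop_config("small_random", small = 24L, n_small_crops = 5L, seed = 9L)
  a <- make_crops(rect, cfg, mrect)
  b <- make_crops(rect, cfg, mrect)
  expect_equal(lapply(a, `[[`, "offset_row"), lapply(b, `[[`, "offset_row"))
  expect_equal(lapply(a, `[[`, "offset_col"), lapply(b, `[[`, "offset_col"))
  expect_true(all(vapply(a, function(cr)
    cr$offset_row >= 1 && cr$offset_row + 24 - 1 <= 64, logical(1))))
  expect_warning(
    small <- make_crops(rect[1:20, 1:20, , drop = FALSE],
                        cfg, mrect[1:20, 1:20]),
    "smaller")
  expect_length(small, 0)
  # resize_full produces the configured square
  cfgf <- crop_config("resize_full", resize_target = 32L)
  f <- make_crops(rect, cfgf, mrect)[[1]]
  expect_equal(dim(f$image), c(32, 32, 3))
})

test_that("the 30% spike-fraction filter is boundary inclusive", {
  mk <- function(n_body) {
    m <- matrix(0L, 128, 128)
    if (n_body > 0) m[seq_len(n_body)] <- 2L
    list(image = array(0, c(128, 128, 3)), mask = m,
         spike_fraction = mean(m == 2L))
  }
  kept <- filter_crops(list(mk(4915L)), min_spike_fraction = 0.30)
  expect_length(kept, 1)        # 4915/16384 >= 0.30
  gone <- filter_crops(list(mk(4914L)), min_spike_fraction = 0.30)
  expect_length(gone, 0)        # 4914/16384 < 0.30
  all_kept <- filter_crops(list(mk(0L), mk(10L)), min_spike_fraction = 0)
  expect_length(all_kept, 2)
})
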