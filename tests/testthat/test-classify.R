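test_that("confusion counts follow the score >= threshold rule", {
  cc <- confusion_counts(c(0.9, 0.1), c(1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 1, FP = 0, FN = 0))
  # boundary: a score of exactly 0.5 predicts the positive class
  cc2 <- confusion_counts(0.5, 0)
  expect_equal(cc2$FP, 1)
  expect_error(confusion_counts(c(0.5), c(2)), "binary")
  expect_error(confusion_counts(c(0.5, 0.1), c(1)), "length")
  # random vectors vs a brute-force per-element tally
  set.seed(15)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    s <- runif(n); l <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(s, l)
    tp <- tn <- fp <- fn <- 0
    for (j in seq_len(n)) {
      p <- if (s[j] >= 0.5) 1 else 0
      if (p == 1 && l[j] == 1) tp <- tp + 1
      if (p == 0 && l[j] == 0) tn <- tn + 1
      if (p == 1 && l[j] == 0) fp <- fp + 1
      if (p == 0 && l[j] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
                 c(TP = tp, TN = tn, FP = fp, FN = fn))
  }
})

test_that("ACC, PR, F1 and AUC follow their formulas", {
  cc <- list(TP = 3, TN = 5, FP = 1, FN = 1, P = 4, N = 6)
  class(cc) <- "sg_confusion"
  m <- compute_metrics(cc)
  expect_equal(m$ACC, 0.8)
  expect_equal(m$PR, 0.75)
  expect_equal(m$F1, 0.75)
  m2 <- compute_metrics(scores = c(0.1, 0.4, 0.35, 0.8),
                        labels = c(0, 0, 1, 1))
  expect_equal(m2$AUC, 0.75)
  expect_equal(compute_metrics(scores = c(0.1, 0.2, 0.8, 0.9),
                               labels = c(0, 0, 1, 1))$AUC, 1)
  # AUC is invariant under strictly monotone transforms and handles ties
  set.seed(77)
  s <- runif(30); l <- rbinom(30, 1, 0.4)
  expect_equal(compute_metrics(scores = s, labels = l)$AUC,
               compute_metrics(scores = plogis(5 * s - 1), labels = l)$AUC)
  st <- round(s, 1)   # force ties
  expect_equal(compute_metrics(scores = st, labels = l)$AUC,
               oracle_auc(st, l))
  # degenerate cases flagged
  expect_true(is.na(compute_metrics(scores = c(0.9, 0.8),
                                    labels = c(1, 1))$AUC))
  cc0 <- list(TP = 0, TN = 4, FP = 0, FN = 0, P = 0, N = 4)
  class(cc0) <- "sg_confusion"
  expect_true(is.na(compute_metrics(cc0)$F1))
})

test_that("package AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    s <- runif(40); l <- c(rbinom(38, 1, 0.5), 0, 1)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(compute_metrics(scores = s, labels = l)$AUC, ref)
  }
})

test_that("image-level prediction passes through or averages crop scores", {
  m <- desk_classifier()
  crop <- desk_crop_pair(desk_holdout_set()$scenes[[1]])$image
  s1 <- cls_score(m, crop)
  expect_equal(predict_image(m, list(crop)), s1)
  crops <- lapply(desk_holdout_set()$scenes[1:3], function(s)
    desk_crop_pair(s)$image)
  ss <- vapply(crops, function(cr) cls_score(m, cr), numeric(1))
  expect_equal(predict_image(m, crops), mean(ss))
  expect_error(predict_image(m, list()), "no-prediction|no crops")
})

test_that("classifier training reduces loss, is seeded, and rejects bad input", {
  tr <- desk_train_set()
  crops <- lapply(tr$scenes[1:16], function(s) desk_crop_pair(s)$image)
  labs <- tr$metadata$pubescence[1:16]
  cfg <- cls_train_config(input_size = 32L, lr = 1e-2, epochs = 8L,
                          batch_size = 16L, seed = 4L)
  m <- train_classifier(crops, labs, cfg)
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
  m2 <- train_classifier(crops, labs, cfg)
  expect_equal(m$log, m2$log, tolerance = 1e-12)
  expect_error(train_classifier(crops, rep(1, length(crops)), cfg),
               "single-class")
  expect_error(cls_train_config(backbone = "efficientnet-b1"), "unsupported")
  expect_error(cls_train_config(pretrained = TRUE), "pretrained")
})

test_that("the compact classifier separates pubescence classes on held-out crops", {
  m <- desk_classifier()
  ho <- desk_holdout_set()
  crops <- lapply(ho$scenes, function(s) desk_crop_pair(s)$image)
  scores <- vapply(crops, function(cr) cls_score(m, cr), numeric(1))
  met <- compute_metrics(scores = scores, labels = ho$metadata$pubescence)
  expect_gte(met$AUC, 0.9)
})

test_that("activation maps satisfy the Grad-CAM contract", {
  m <- desk_classifier()
  ho <- desk_holdout_set()
  crop <- desk_crop_pair(ho$scenes[[1]])$image
  cam <- activation_map(m, crop)
  expect_equal(dim(cam), dim(crop)[1:2])
  expect_true(all(cam >= 0 & cam <= 1))
  expect_false(attr(cam, "all_zero"))
  # zero head weights give a flagged all-zero map
  m0 <- m
  m0$params$w_mean[] <- 0
  m0$params$w_max[] <- 0
  cam0 <- activation_map(m0, crop)
  expect_true(attr(cam0, "all_zero"))
  expect_true(all(cam0 == 0))
})

test_that("activation concentrates on the spike edge band for haired crops", {
  m <- desk_classifier()
  ho <- desk_holdout_set()
  hits <- 0; total <- 0
  for (i in seq_along(ho$scenes)) {
    if (ho$metadata$pubescence[i] != 1L) next
    pair <- desk_crop_pair(ho$scenes[[i]])
    sc <- cls_score(m, pair$image)
    if (sc < 0.5) next                      # only correctly classified crops
    total <- total + 1
    eb <- edge_band(pair$mask)
    cam <- activation_map(m, pair$image)
    if (mean(cam[eb$band]) > mean(cam[eb$interior])) hits <- hits + 1
  }
  expect_gt(total, 0)
  expect_gte(hits / total, 0.7)
})
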