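# Shared desk-scale fixtures. Heavy artifacts (trained models, generated
# scene sets) are built once per test run and cached.

sg_cache <- new.env(parent = emptyenv())

sg_cached <- function(name, fn) {
  if (is.null(sg_cache[[name]])) assign(name, fn(), envir = sg_cache)
  get(name, envir = sg_cache)
}

desk_phantom_config <- function(...) {
  phantom_config(scene_height = 144, scene_width = 96, allow_small = TRUE,
                 colorchecker_area_range = c(120, 320), ...)
}

desk_tiling <- function() tiling_config(tile_size = 96L, stride = 48L)

desk_train_set <- function() sg_cached("train_set", function()
  generate_dataset(desk_phantom_config(), 64, seed = 21))

desk_holdout_set <- function() sg_cached("holdout_set", function()
  generate_dataset(desk_phantom_config(), 32, seed = 22))

desk_eval_set <- function() sg_cached("eval_set", function()
  generate_dataset(desk_phantom_config(), 80, seed = 55))

# medium central crop (and its mask) from a ground-truth-masked scene
desk_crop_pair <- function(s, medium = 96L) {
  rect <- blackout_background(s$scene$image, s$mask)
  make_crops(rect$image, crop_config("medium_central", medium = medium),
             rect$mask)[[1]]
}

desk_segmenter <- function() sg_cached("segmenter", function()
  train_segmenter(desk_train_set(),
                  seg_train_config(tiling = desk_tiling(), lr = 2e-3,
                                   epochs = 8L, batch_size = 8L,
                                   augment = FALSE, seed = 5L)))

desk_classifier <- function() sg_cached("classifier", function() {
  tr <- desk_train_set()
  crops <- lapply(tr$scenes, function(s) desk_crop_pair(s)$image)
  train_classifier(crops, tr$metadata$pubescence,
                   cls_train_config(input_size = 64L, lr = 2e-2,
                                    epochs = 80L, batch_size = 64L,
                                    seed = 1L))
})

# Independent 5-px inner edge band of the spike body, by iterated
# 4-neighbour erosion (no package geometry code involved).
edge_band <- function(mask, width = 5L) {
  body <- mask == 2L
  er <- body
  for (i in seq_len(width)) {
    e <- er
    e[-1, ] <- e[-1, ] & er[-nrow(er), ]
    e[-nrow(e), ] <- e[-nrow(e), ] & er[-1, ]
    e[, -1] <- e[, -1] & er[, -ncol(er)]
    e[, -ncol(e)] <- e[, -ncol(e)] & er[, -1]
    er <- e
  }
  list(band = body & !er, interior = er)
}

# brute-force rank AUC used as an oracle in several files
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}
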