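test_that("scene generation is bit-reproducible under a fixed seed", {
  cfg <- desk_phantom_config()
  a <- generate_scene(cfg, species_id = "spA", pubescence = 1L, seed = 42)
  b <- generate_scene(cfg, species_id = "spA", pubescence = 1L, seed = 42)
  expect_identical(a, b)
  d <- generate_dataset(cfg, 6, seed = 9)
  d2 <- generate_dataset(cfg, 6, seed = 9)
  expect_identical(d, d2)
})

test_that("masks carry exactly the painted structures", {
  cfg <- desk_phantom_config()
  sc <- generate_scene(cfg, pubescence = 1L, seed = 7)
  expect_true(all(sc$mask %in% 0:3))
  expect_identical(dim(sc$mask), dim(sc$scene$image)[1:2])
  # the color target is one solid rectangle and its reported area is exact
  idx <- which(sc$mask == 1L, arr.ind = TRUE)
  expect_equal(nrow(idx), sc$scene$colorchecker_area)
  expect_equal(nrow(idx), diff(range(idx[, 1]) + c(0, 1)) *
                 diff(range(idx[, 2]) + c(0, 1)))
  # awns can be disabled exactly
  cfg0 <- desk_phantom_config(awn_count_range = c(0L, 0L))
  sc0 <- generate_scene(cfg0, pubescence = 0L, seed = 7)
  expect_equal(sum(sc0$mask == 3L), 0)
})

test_that("scene too small for the body template is refused", {
  expect_error(phantom_config(scene_height = 40, scene_width = 30,
                              allow_small = TRUE), "too small")
  expect_error(phantom_config(scene_height = 400, scene_width = 400),
               "512")
})

test_that("zero hair amplitude removes the class signal entirely", {
  cfg_h <- desk_phantom_config(hair_texture_amplitude = 0,
                               haired_fraction_per_species = 1)
  cfg_g <- desk_phantom_config(hair_texture_amplitude = 0,
                               haired_fraction_per_species = 0)
  dh <- generate_dataset(cfg_h, 8, seed = 31)
  dg <- generate_dataset(cfg_g, 8, seed = 31)
  stat <- function(d) mean(sapply(d$scenes, function(s) {
    eb <- edge_band(s$mask)
    gray <- (s$scene$image[, , 1] + s$scene$image[, , 2] +
               s$scene$image[, , 3]) / 3
    var(gray[eb$band])
  }))
  vh <- stat(dh); vg <- stat(dg)
  expect_lt(abs(vh - vg) / vg, 0.01)
})

test_that("edge-band texture variance separates the classes at default amplitude", {
  d <- desk_eval_set()
  v <- sapply(d$scenes, function(s) {
    eb <- edge_band(s$mask)
    gray <- (s$scene$image[, , 1] + s$scene$image[, , 2] +
               s$scene$image[, , 3]) / 3
    var(gray[eb$band])
  })
  expect_gte(oracle_auc(v, d$metadata$pubescence), 0.9)
})

test_that("dataset metadata follows the round-robin and label law", {
  cfg <- desk_phantom_config(n_species = 3)
  d <- generate_dataset(cfg, 12, seed = 3)
  expect_equal(nrow(d$metadata), 12)
  expect_equal(unname(table(d$metadata$species_id)), rep(4L, 3),
               ignore_attr = TRUE)
  cfg1 <- desk_phantom_config(n_species = 2, haired_fraction_per_species = 1)
  d1 <- generate_dataset(cfg1, 8, seed = 3)
  expect_true(all(d1$metadata$pubescence == 1L))
  expect_error(generate_dataset(cfg, 2, seed = 1), "n_species")
  # binomial law at p = 0.5: count within 3 SD over n = 200
  cfg2 <- phantom_config(80, 56, allow_small = TRUE, n_species = 1,
                         haired_fraction_per_species = 0.5,
                         colorchecker_area_range = c(48, 80),
                         awn_count_range = c(1L, 3L))
  d2 <- generate_dataset(cfg2, 200, seed = 17)
  x <- sum(d2$metadata$pubescence)
  expect_lt(abs(x - 100), 3 * sqrt(200 * 0.25))
})

test_that("dataset files round-trip exactly through PNG and CSV", {
  dir <- withr::local_tempdir()
  cfg <- desk_phantom_config()
  d <- generate_dataset(cfg, 4, seed = 13, dir = dir)
  id <- d$metadata$image_id[2]
  img <- read_image_png(file.path(dir, paste0(id, ".png")))
  msk <- read_mask_png(file.path(dir, paste0(id, "_mask.png")))
  expect_identical(img, d$scenes[[2]]$scene$image)
  expect_identical(msk, d$scenes[[2]]$mask)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(meta$colorchecker_area, d$metadata$colorchecker_area)
})

test_that("species tables conserve their specification", {
  tab <- wheat_species_composition()
  expect_equal(nrow(tab), 19)
  expect_equal(sum(tab$n_haired) + sum(tab$n_hairless), 9679)
  expect_equal(round(attr(tab, "k"), 2), 1.77)
  r <- generate_species_table(5, list(total_haired = 120, total_hairless = 300),
                              seed = 4)
  expect_equal(sum(r$n_haired), 120)
  expect_equal(sum(r$n_hairless), 300)
  expect_error(generate_species_table(1, data.frame(n_haired = -1,
                                                    n_hairless = 2)),
               "non-negative")
  one <- generate_species_table(1, data.frame(n_haired = 10, n_hairless = 0))
  expect_false(attr(one, "k_defined"))
})
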