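# Synthetic spike-scene ("phantom") generator.
#
# A phantom scene emulates the layout of a laboratory spike photograph: a
# uniform background, one rectangular color-reference target, a vertically
# elongated spike body with a serrated contour, and thin awn filaments rising
# from the spike tip. Glume pubescence is encoded as a high-frequency
# hair-stroke texture painted along the inner edge band of the spike body;
# glabrous phantoms have smooth edges. The class mask is constructed first
# and the image is painted from it, so mask/image correspondence is exact by
# construction.

#' Configuration for the phantom scene generator
#'
#' @param scene_height,scene_width scene size in px. Sizes below 512 (the
#'   default segmentation tile) are refused unless `allow_small = TRUE`,
#'   in which case downstream tiling pads symmetrically with zeros.
#' @param n_species number of synthetic species labels.
#' @param haired_fraction_per_species probability that a scene of each species
#'   is pubescent; recycled to `n_species`.
#' @param hair_texture_amplitude intensity amplitude (0..255 units) of the
#'   hair strokes painted along the spike-body edge band of pubescent scenes.
#'   Amplitude 0 makes pubescent and glabrous scenes statistically identical.
#' @param awn_count_range integer `(min, max)` number of awn filaments.
#' @param colorchecker_area_range `(min, max)` area in px^2 of the color
#'   target rectangle; the realized area is reported per scene and serves as
#'   the magnification proxy.
#' @param background_color RGB triple in 0..255.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param allow_small permit scenes smaller than 512 px (desk-scale work).
#' @param seed optional integer seed stored in the config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(scene_height = 640, scene_width = 512,
                           n_species = 3,
                           haired_fraction_per_species = 0.5,
                           hair_texture_amplitude = 55,
                           awn_count_range = c(3L, 8L),
                           colorchecker_area_range = c(3000, 8000),
                           background_color = c(205, 205, 200),
                           noise_sd = 4,
                           allow_small = FALSE,
                           seed = NULL) {
  if (!allow_small && (scene_height < 512 || scene_width < 512))
    stop("scene dimensions must be >= 512 px unless `allow_small = TRUE`",
         call. = FALSE)
  if (scene_height < 64 || scene_width < 48)
    stop("scene too small for the spike body template (min 64 x 48 px)",
         call. = FALSE)
  hf <- rep_len(haired_fraction_per_species, n_species)
  if (any(hf < 0 | hf > 1))
    stop("haired_fraction_per_species must lie in [0, 1]", call. = FALSE)
  if (length(awn_count_range) != 2L || any(awn_count_range < 0) ||
      awn_count_range[1] > awn_count_range[2])
    stop("awn_count_range must be a non-negative (min, max) pair", call. = FALSE)
  if (length(colorchecker_area_range) != 2L || colorchecker_area_range[1] <= 0 ||
      colorchecker_area_range[1] > colorchecker_area_range[2])
    stop("colorchecker_area_range must be positive with min <= max", call. = FALSE)
  structure(list(
    scene_height = as.integer(scene_height),
    scene_width = as.integer(scene_width),
    n_species = as.integer(n_species),
    haired_fraction_per_species = hf,
    hair_texture_amplitude = hair_texture_amplitude,
    awn_count_range = as.integer(awn_count_range),
    colorchecker_area_range = colorchecker_area_range,
    background_color = background_color,
    noise_sd = noise_sd,
    allow_small = allow_small,
    seed = seed
  ), class = "phantom_config")
}

# Spike-body geometry: a vertically elongated superellipse with a sinusoidal
# serration of its half-width. Returns per-row left/right column bounds
# (NA outside the body) plus the inside indicator matrix.
body_geometry <- function(H, W) {
  cy <- H * 0.52
  cx <- W * 0.62
  a <- H * 0.40            # vertical semi-axis
  b <- min(W * 0.16, W - cx - 2, cx - 2)  # horizontal semi-axis
  n <- 2.5                 # superellipse exponent (convex-ish)
  rows <- seq_len(H)
  dr <- rows - cy
  serr <- 1 + 0.06 * sin(2 * pi * dr / (H / 12))   # serrated edge
  inside_amp <- 1 - abs(dr / a)^n
  half <- ifelse(inside_amp > 0, b * serr * inside_amp^(1 / n), NA_real_)
  cl <- pmax(1, ceiling(cx - half))
  cr <- pmin(W, floor(cx + half))
  cl[is.na(half) | cl > cr] <- NA
  cr[is.na(cl)] <- NA
  list(cl = cl, cr = cr, cx = cx, cy = cy, a = a, b = b)
}

# 24-patch color palette (4 x 6) used to fill the synthetic color target.
TARGET_PALETTE <- matrix(c(
  115,  82,  68,  194, 150, 130,   98, 122, 157,   87, 108,  67,
  133, 128, 177,  103, 189, 170,  214, 126,  44,   80,  91, 166,
  193,  90,  99,   94,  60, 108,  157, 188,  64,  224, 163,  46,
   56,  61, 150,   70, 148,  73,  175,  54,  60,  231, 199,  31,
  187,  86, 149,    8, 133, 161,  243, 243, 242,  200, 200, 200,
  160, 160, 160,  122, 122, 121,   85,  85,  85,   52,  52,  52
), ncol = 3, byrow = TRUE)

#' Generate one synthetic spike scene with its ground-truth mask
#'
#' @param config a [phantom_config()].
#' @param species_id species label stored in the scene metadata.
#' @param pubescence 0 (glabrous) or 1 (pubescent).
#' @param seed optional integer; when given, the RNG is seeded so that the
#'   same `(config, seed)` pair is bit-reproducible.
#' @param image_id identifier stored in the metadata.
#' @return A list with elements `scene` (class `sg_scene`: `image`,
#'   `image_id`, `species_id`, `pubescence`, `resolution_tag`,
#'   `colorchecker_area`) and `mask` (integer matrix, labels 0-3).
#' @export
generate_scene <- function(config, species_id = "sp1", pubescence = 0L,
                           seed = NULL, image_id = "img1") {
  stopifnot(inherits(config, "phantom_config"))
  if (!pubescence %in% c(0L, 1L)) stop("pubescence must be 0 or 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  H <- config$scene_height; W <- config$scene_width

  geo <- body_geometry(H, W)
  mask <- matrix(0L, H, W)
  body_rows <- which(!is.na(geo$cl))
  for (r in body_rows) mask[r, geo$cl[r]:geo$cr[r]] <- 2L

  # color target in the clear region left of the body
  area <- runif(1, config$colorchecker_area_range[1], config$colorchecker_area_range[2])
  tw <- max(6L, as.integer(round(sqrt(area * 1.5))))
  th <- max(4L, as.integer(round(area / tw)))
  left_limit <- min(geo$cl[body_rows], na.rm = TRUE) - 3L
  if (tw + 4L > left_limit || th + 4L > H - 4L)
    stop("scene too small for the requested color-target area", call. = FALSE)
  t_r0 <- as.integer(round(runif(1, 3, H - th - 2)))
  t_c0 <- as.integer(round(runif(1, 3, left_limit - tw)))
  mask[t_r0:(t_r0 + th - 1L), t_c0:(t_c0 + tw - 1L)] <- 1L
  realized_area <- as.integer(th) * as.integer(tw)

  # awns: thin filaments rising from the spike tip, painted over background
  n_awn <- if (config$awn_count_range[2] > config$awn_count_range[1])
    sample(config$awn_count_range[1]:config$awn_count_range[2], 1L)
  else config$awn_count_range[1]
  if (n_awn > 0) {
    top_row <- min(body_rows)
    for (i in seq_len(n_awn)) {
      c0 <- as.integer(round(geo$cx + runif(1, -0.7, 0.7) * geo$b))
      r_anchor <- top_row
      for (r in seq(max(1, top_row - 2), min(H, top_row + round(0.1 * H)))) {
        if (!is.na(geo$cl[r]) && c0 >= geo$cl[r] && c0 <= geo$cr[r]) { r_anchor <- r; break }
      }
      len <- as.integer(round(runif(1, 0.18, 0.38) * H))
      curv <- runif(1, -0.25, 0.25)
      slope <- runif(1, -0.3, 0.3)
      s <- seq_len(len)
      rr <- r_anchor - s
      cc <- as.integer(round(c0 + slope * s + curv * (s / len)^2 * len * 0.3))
      keep <- rr >= 1 & cc >= 1 & cc <= W
      rr <- rr[keep]; cc <- cc[keep]
      idx <- cbind(rr, cc)
      paintable <- mask[idx] == 0L
      mask[idx[paintable, , drop = FALSE]] <- 3L
    }
  }

  # paint the image from the mask
  img <- array(0, c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- config$background_color[ch] + rnorm(H * W, 0, config$noise_sd)

  body_idx <- which(mask == 2L)
  if (length(body_idx)) {
    rr <- ((body_idx - 1L) %% H) + 1L
    base <- c(150, 118, 66)
    band <- 16 * sin(2 * pi * (rr - geo$cy) / (H / 9))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[body_idx] <- base[ch] + band + rnorm(length(body_idx), 0, config$noise_sd + 2)
      img[, , ch] <- plane
    }
  }

  awn_idx <- which(mask == 3L)
  if (length(awn_idx)) {
    base <- c(95, 78, 45)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[awn_idx] <- base[ch] + rnorm(length(awn_idx), 0, config$noise_sd + 1)
      img[, , ch] <- plane
    }
  }

  t_rows <- t_r0:(t_r0 + th - 1L); t_cols <- t_c0:(t_c0 + tw - 1L)
  patch_r <- pmin(4L, th); patch_c <- pmin(6L, tw)
  pr <- as.integer(cut(seq_along(t_rows), patch_r, labels = FALSE))
  pc <- as.integer(cut(seq_along(t_cols), patch_c, labels = FALSE))
  pal_idx <- outer(pr, pc, function(i, j) (i - 1L) * 6L + j)
  pal_idx[pal_idx > nrow(TARGET_PALETTE)] <- nrow(TARGET_PALETTE)
  border <- outer(seq_along(t_rows), seq_along(t_cols), function(i, j)
    i <= 1 | j <= 1 | i >= length(t_rows) | j >= length(t_cols))
  for (ch in 1:3) {
    patch_vals <- matrix(TARGET_PALETTE[pal_idx, ch], length(t_rows), length(t_cols))
    patch_vals[border] <- 245
    img[t_rows, t_cols, ch] <- patch_vals +
      rnorm(length(patch_vals), 0, config$noise_sd / 2)
  }

  # pubescence: additive hair strokes along the inner 5-px edge band of the
  # body. Additive so that amplitude 0 is an exact no-op; the signal is
  # painted only on body pixels, leaving the mask untouched.
  if (pubescence == 1L && config$hair_texture_amplitude != 0) {
    amp <- config$hair_texture_amplitude
    for (r in body_rows) {
      for (side in c("l", "r")) {
        if (runif(1) > 0.75) next
        len <- sample(3:6, 1L)
        sgn <- sample(c(-1, 1), 1L)
        if (side == "l") cols <- geo$cl[r]:min(geo$cl[r] + len - 1L, geo$cr[r])
        else cols <- max(geo$cl[r], geo$cr[r] - len + 1L):geo$cr[r]
        taper <- seq(1, 0.4, length.out = length(cols))
        if (side == "r") taper <- rev(taper)
        for (ch in 1:3) img[r, cols, ch] <- img[r, cols, ch] + sgn * amp * taper
      }
    }
  }

  img <- array(as.integer(round_half_up(clamp255(img))), c(H, W, 3))
  scene <- structure(list(
    image = img,
    image_id = image_id,
    species_id = species_id,
    pubescence = as.integer(pubescence),
    resolution_tag = "15Mp-like",
    colorchecker_area = realized_area
  ), class = "sg_scene")
  list(scene = scene, mask = mask)
}

#' Generate a phantom dataset with metadata
#'
#' Species are assigned round-robin; the pubescence label of each scene is
#' drawn from the per-species haired fraction in the config; the resolution
#' tag alternates between the two emulated sensor formats.
#'
#' @param config a [phantom_config()].
#' @param n_images number of scenes (must be >= `n_species` so every species
#'   is represented).
#' @param seed integer seed controlling everything drawn here.
#' @param dir optional directory; when given, images (`<id>.png`), masks
#'   (`<id>_mask.png`) and `metadata.csv` are written there.
#' @return A list with `scenes` (list of `(scene, mask)` pairs) and
#'   `metadata` (data.frame: image_id, species_id, pubescence,
#'   resolution_tag, colorchecker_area).
#' @export
generate_dataset <- function(config, n_images, seed = 1L, dir = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_images < 1) stop("n_images must be >= 1", call. = FALSE)
  if (n_images < config$n_species)
    stop("n_images < n_species: every species must be represented at least once",
         call. = FALSE)
  set.seed(seed)
  species <- paste0("sp", ((seq_len(n_images) - 1L) %% config$n_species) + 1L)
  hf <- config$haired_fraction_per_species[((seq_len(n_images) - 1L) %%
                                              config$n_species) + 1L]
  pub <- rbinom(n_images, 1L, hf)
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  scenes <- vector("list", n_images)
  meta <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("phantom_%04d", i)
    sc <- generate_scene(config, species_id = species[i], pubescence = pub[i],
                         seed = scene_seeds[i], image_id = id)
    sc$scene$resolution_tag <- if (i %% 2L == 1L) "15Mp-like" else "18Mp-like"
    scenes[[i]] <- sc
    meta[[i]] <- data.frame(
      image_id = id, species_id = species[i], pubescence = pub[i],
      resolution_tag = sc$scene$resolution_tag,
      colorchecker_area = sc$scene$colorchecker_area,
      stringsAsFactors = FALSE
    )
  }
  metadata <- do.call(rbind, meta)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sc in scenes) {
      write_image_png(sc$scene$image, file.path(dir, paste0(sc$scene$image_id, ".png")))
      write_mask_png(sc$mask, file.path(dir, paste0(sc$scene$image_id, "_mask.png")))
    }
    write.csv(metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  list(scenes = scenes, metadata = metadata)
}

#' Build a species table of per-species class counts
#'
#' Either pass exact per-species counts, or totals to be spread randomly
#' across species (useful for emulating a collection's composition when only
#' the class totals are known).
#'
#' @param n_species number of species rows.
#' @param counts_spec either a data.frame with columns `n_haired`,
#'   `n_hairless` (and optionally `species_id`), or a list
#'   `list(total_haired =, total_hairless =)` whose totals are distributed
#'   across species by a seeded multinomial draw.
#' @param seed seed for the random distribution path.
#' @return A data.frame of class `sg_species_table` with columns
#'   `species_id`, `n_haired`, `n_hairless`, and attributes `k` (overall
#'   hairless/haired ratio, `NA` when undefined) and `k_defined`.
#' @export
generate_species_table <- function(n_species, counts_spec, seed = 1L) {
  if (is.data.frame(counts_spec)) {
    if (!all(c("n_haired", "n_hairless") %in% names(counts_spec)))
      stop("counts_spec data.frame needs columns n_haired, n_hairless", call. = FALSE)
    tab <- counts_spec
    if (is.null(tab$species_id)) tab$species_id <- paste0("sp", seq_len(nrow(tab)))
    if (nrow(tab) != n_species)
      stop("counts_spec has ", nrow(tab), " rows but n_species = ", n_species,
           call. = FALSE)
  } else if (is.list(counts_spec)) {
    set.seed(seed)
    th <- counts_spec$total_haired; tn <- counts_spec$total_hairless
    if (is.null(th) || is.null(tn))
      stop("counts_spec list needs total_haired and total_hairless", call. = FALSE)
    w <- runif(n_species, 0.2, 1)
    tab <- data.frame(
      species_id = paste0("sp", seq_len(n_species)),
      n_haired = as.vector(stats::rmultinom(1, th, w)),
      n_hairless = as.vector(stats::rmultinom(1, tn, w))
    )
  } else stop("counts_spec must be a data.frame or a list of totals", call. = FALSE)
  if (any(tab$n_haired < 0 | tab$n_hairless < 0))
    stop("species counts must be non-negative", call. = FALSE)
  if (sum(tab$n_haired + tab$n_hairless) == 0)
    stop("at least one species must have a positive total", call. = FALSE)
  tab <- tab[, c("species_id", "n_haired", "n_hairless")]
  total_h <- sum(tab$n_haired)
  k <- compute_k(total_h, sum(tab$n_hairless))
  structure(tab, class = c("sg_species_table", "data.frame"),
            k = k, k_defined = !is.na(k) && sum(tab$n_hairless) > 0)
}

#' Synthetic species composition emulating a diverse wheat collection
#'
#' A fixed 19-species table whose class totals equal 3,499 pubescent and
#' 6,180 glabrous images (hairless/haired ratio k = 1.77) and whose
#' per-species profiles mimic a real collection: one all-glabrous species,
#' three all-pubescent species, nine glabrous-dominated species (including
#' one large species holding more than 10% of all images, which the
#' stratification rules therefore force into the training subsample) and
#' six mixed species whose internal class ratio sits close to the
#' collection-wide ratio, so that species-atomic subsamples preserving k
#' exist - the property the randomized stratification relies on. The
#' composition is synthetic: it matches the class totals and qualitative
#' species profile of a published collection, not its per-species counts,
#' which are not public.
#'
#' @return An `sg_species_table` (see [generate_species_table()]).
#' @export
wheat_species_composition <- function() {
  tab <- data.frame(
    species_id = c(
      "T_compactum", "T_timopheevii", "T_vavilovii", "T_petropavlovskyi",
      "T_aestivum", "T_monococcum", "T_urartu", "T_spelta", "T_macha",
      "T_turgidum", "T_dicoccum", "T_aethiopicum", "T_polonicum",
      "T_beoticum", "T_durum", "T_dicoccoides", "T_sphaerococcum",
      "T_carthlicum", "T_yunnanense"
    ),
    n_haired = c(
      0, 430, 370, 230,
      180, 40, 25, 60, 45, 70, 75, 40, 50,
      350, 330, 300, 280, 254, 370
    ),
    n_hairless = c(
      420, 0, 0, 0,
      1020, 175, 120, 240, 155, 235, 255, 115, 117,
      619, 583, 530, 494, 449, 653
    )
  )
  generate_species_table(nrow(tab), tab)
}
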