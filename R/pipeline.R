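# End-to-end pipeline orchestration.
#
# Stages: phantom -> stratify -> train_seg -> predict -> extract ->
# train_cls -> eval -> robustness. Every stage reads only artifacts written
# by earlier stages, writes its outputs plus a JSON manifest (inputs,
# outputs, stage seed, config hash) under the output root, and a missing
# upstream artifact raises a dependency error naming the absent file. A
# single global seed fans out to fixed per-stage seeds, so identical
# config + seed reproduce identical artifacts.

PIPELINE_STAGES <- c("phantom", "stratify", "train_seg", "predict",
                     "extract", "train_cls", "eval", "robustness")

stage_seed <- function(global_seed, stage) {
  idx <- match(stage, PIPELINE_STAGES)
  as.integer((as.numeric(global_seed) + idx * 10007) %% 2147483611)
}

config_md5 <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

require_artifact <- function(path) {
  if (!file.exists(path))
    stop("dependency error: missing upstream artifact '", path, "'",
         call. = FALSE)
  path
}

write_manifest <- function(out_root, stage, inputs, outputs, seed, config) {
  man <- list(stage = stage, inputs = inputs, outputs = outputs,
              seed = seed, config_md5 = config_md5(config))
  path <- file.path(out_root, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

#' Desk-scale pipeline configuration
#'
#' Defaults describe a small synthetic study that runs on one CPU in
#' minutes: 120 phantom scenes of 144 x 96 px, the compact segmenter and
#' classifier, medium central crops scaled to the phantom size, and a
#' reduced distortion sweep.
#'
#' @param out_root output directory of the run.
#' @param seed global seed fanned out to per-stage seeds.
#' @param stages subset of the stage list to execute, in pipeline order.
#' @param n_images number of phantom scenes.
#' @param phantom a [phantom_config()].
#' @param tiling a [tiling_config()] (desk default: 96/48).
#' @param seg a [seg_train_config()].
#' @param crop a [crop_config()] (desk default: medium 96 central crop).
#' @param cls a [cls_train_config()].
#' @param distortion a [distortion_config()].
#' @param use_reference_masks robustness stage reuses clean ground-truth
#'   masks instead of re-segmenting distorted scenes.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_root,
                       seed = 1L,
                       stages = PIPELINE_STAGES,
                       n_images = 120L,
                       phantom = phantom_config(scene_height = 144,
                                                scene_width = 96,
                                                colorchecker_area_range = c(120, 320),
                                                allow_small = TRUE),
                       tiling = tiling_config(tile_size = 96L, stride = 48L),
                       seg = seg_train_config(tiling = tiling_config(96L, 48L),
                                              lr = 2e-3, epochs = 8L,
                                              augment = FALSE),
                       crop = crop_config(strategy = "medium_central",
                                          medium = 96L),
                       cls = cls_train_config(input_size = 64L, lr = 2e-2,
                                              epochs = 80L, batch_size = 64L),
                       distortion = distortion_config(blur_kernel_sizes = c(2L, 4L),
                                                      brightness_deltas = c(40, -40)),
                       use_reference_masks = FALSE) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  structure(list(out_root = out_root, seed = as.integer(seed),
                 stages = stages[order(match(stages, PIPELINE_STAGES))],
                 n_images = as.integer(n_images), phantom = phantom,
                 tiling = tiling, seg = seg, crop = crop, cls = cls,
                 distortion = distortion,
                 use_reference_masks = isTRUE(use_reference_masks)),
            class = "run_config")
}

read_phantom_dir <- function(dir) {
  meta <- read.csv(require_artifact(file.path(dir, "metadata.csv")),
                   stringsAsFactors = FALSE)
  scenes <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$image_id[i]
    img <- read_image_png(require_artifact(file.path(dir, paste0(id, ".png"))))
    msk <- read_mask_png(require_artifact(file.path(dir, paste0(id, "_mask.png"))))
    list(scene = structure(list(image = img, image_id = id,
                                species_id = meta$species_id[i],
                                pubescence = meta$pubescence[i],
                                resolution_tag = meta$resolution_tag[i],
                                colorchecker_area = meta$colorchecker_area[i]),
                           class = "sg_scene"),
         mask = msk)
  })
  list(scenes = scenes, metadata = meta)
}

species_of_subset <- function(split_csv, subset) {
  sp <- read.csv(require_artifact(split_csv), stringsAsFactors = FALSE)
  sp$species_id[sp$subsample %in% subset]
}

#' Run the end-to-end pipeline
#'
#' Executes the configured stages in order, writing per-stage artifacts and
#' manifests under `cfg$out_root`. See [run_config()] for the stage
#' defaults. The run halts at the first failing stage; completed stages
#' leave their manifests, so a rerun restricted to later stages resumes
#' from the checkpoint.
#'
#' @param cfg a [run_config()].
#' @return Named list of manifest paths, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  root <- cfg$out_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  phantom_dir <- file.path(root, "phantom")
  split_dir <- file.path(root, "stratify")
  seg_dir <- file.path(root, "seg_model")
  pred_dir <- file.path(root, "pred_masks")
  crops_dir <- file.path(root, "crops")
  cls_dir <- file.path(root, "cls_model")

  for (stage in cfg$stages) {
    sseed <- stage_seed(cfg$seed, stage)
    if (stage == "phantom") {
      generate_dataset(cfg$phantom, cfg$n_images, seed = sseed,
                       dir = phantom_dir)
      manifests[[stage]] <- write_manifest(
        root, stage, inputs = character(0),
        outputs = file.path(phantom_dir, "metadata.csv"),
        seed = sseed, config = cfg$phantom)
    } else if (stage == "stratify") {
      meta_csv <- require_artifact(file.path(phantom_dir, "metadata.csv"))
      meta <- read.csv(meta_csv, stringsAsFactors = FALSE)
      tab <- metadata_to_species_table(meta)
      scfg <- stratify_config(seed = sseed)
      split <- stratify_balanced_by_class(tab, scfg, audit = FALSE)
      write_split(split, split_dir, seed = sseed)
      manifests[[stage]] <- write_manifest(
        root, stage, inputs = meta_csv,
        outputs = file.path(split_dir, c("split.csv", "summary.json")),
        seed = sseed, config = scfg)
    } else if (stage == "train_seg") {
      ph <- read_phantom_dir(phantom_dir)
      train_sp <- species_of_subset(file.path(split_dir, "split.csv"), "train")
      pairs <- Filter(function(s) s$scene$species_id %in% train_sp, ph$scenes)
      seg_cfg <- cfg$seg; seg_cfg$seed <- sseed
      model <- train_segmenter(pairs, seg_cfg)
      save_model(model, seg_dir)
      manifests[[stage]] <- write_manifest(
        root, stage,
        inputs = c(file.path(phantom_dir, "metadata.csv"),
                   file.path(split_dir, "split.csv")),
        outputs = file.path(seg_dir, "weights.rds"),
        seed = sseed, config = seg_cfg[setdiff(names(seg_cfg), "tiling")])
    } else if (stage == "predict") {
      ph <- read_phantom_dir(phantom_dir)
      require_artifact(file.path(seg_dir, "weights.rds"))
      model <- load_model(seg_dir)
      dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)
      preds <- list(); refs <- list()
      for (s in ph$scenes) {
        pm <- segment_scene(model, s$scene$image, cfg$tiling)
        write_mask_png(pm, file.path(pred_dir, paste0(s$scene$image_id, "_pred.png")))
        preds[[length(preds) + 1L]] <- pm
        refs[[length(refs) + 1L]] <- s$mask
      }
      rep <- iou_report(preds, refs)
      write.csv(rep, file.path(pred_dir, "iou.csv"), row.names = FALSE)
      manifests[[stage]] <- write_manifest(
        root, stage, inputs = file.path(seg_dir, "weights.rds"),
        outputs = file.path(pred_dir, "iou.csv"),
        seed = sseed, config = cfg$tiling)
    } else if (stage == "extract") {
      ph <- read_phantom_dir(phantom_dir)
      dir.create(crops_dir, recursive = TRUE, showWarnings = FALSE)
      crop_cfg <- cfg$crop; crop_cfg$seed <- sseed
      man_rows <- list()
      for (s in ph$scenes) {
        id <- s$scene$image_id
        pm <- read_mask_png(require_artifact(
          file.path(pred_dir, paste0(id, "_pred.png"))))
        bb <- tryCatch(extract_bbox(pm), error = function(e) NULL)
        if (is.null(bb)) next
        rect <- blackout_background(s$scene$image, pm, bb)
        crops <- make_crops(rect$image, crop_cfg, rect$mask)
        for (j in seq_along(crops)) {
          cid <- sprintf("%s_c%02d", id, j)
          write_image_png(crops[[j]]$image, file.path(crops_dir, paste0(cid, ".png")))
          man_rows[[length(man_rows) + 1L]] <- data.frame(
            crop_id = cid, image_id = id, strategy = crop_cfg$strategy,
            offset_row = crops[[j]]$offset_row,
            offset_col = crops[[j]]$offset_col,
            spike_fraction = crops[[j]]$spike_fraction)
        }
      }
      write.csv(do.call(rbind, man_rows), file.path(crops_dir, "crops.csv"),
                row.names = FALSE)
      manifests[[stage]] <- write_manifest(
        root, stage, inputs = file.path(pred_dir, "iou.csv"),
        outputs = file.path(crops_dir, "crops.csv"),
        seed = sseed, config = crop_cfg)
    } else if (stage == "train_cls") {
      meta <- read.csv(require_artifact(file.path(phantom_dir, "metadata.csv")),
                       stringsAsFactors = FALSE)
      cropman <- read.csv(require_artifact(file.path(crops_dir, "crops.csv")),
                          stringsAsFactors = FALSE)
      train_sp <- species_of_subset(file.path(split_dir, "split.csv"), "train")
      val_sp <- species_of_subset(file.path(split_dir, "split.csv"), "val")
      lab <- setNames(meta$pubescence, meta$image_id)
      spc <- setNames(meta$species_id, meta$image_id)
      load_crop <- function(cid) read_image_png(file.path(crops_dir, paste0(cid, ".png")))
      tr <- cropman[spc[cropman$image_id] %in% train_sp, ]
      va <- cropman[spc[cropman$image_id] %in% val_sp, ]
      cls_cfg <- cfg$cls; cls_cfg$seed <- sseed
      model <- train_classifier(lapply(tr$crop_id, load_crop),
                                lab[tr$image_id], cls_cfg,
                                val_crops = if (nrow(va)) lapply(va$crop_id, load_crop),
                                val_labels = if (nrow(va)) lab[va$image_id])
      save_model(model, cls_dir)
      manifests[[stage]] <- write_manifest(
        root, stage,
        inputs = c(file.path(crops_dir, "crops.csv"),
                   file.path(split_dir, "split.csv")),
        outputs = file.path(cls_dir, "weights.rds"),
        seed = sseed, config = cls_cfg)
    } else if (stage == "eval") {
      meta <- read.csv(require_artifact(file.path(phantom_dir, "metadata.csv")),
                       stringsAsFactors = FALSE)
      cropman <- read.csv(require_artifact(file.path(crops_dir, "crops.csv")),
                          stringsAsFactors = FALSE)
      require_artifact(file.path(cls_dir, "weights.rds"))
      model <- load_model(cls_dir)
      lab <- setNames(meta$pubescence, meta$image_id)
      spc <- setNames(meta$species_id, meta$image_id)
      rows <- lapply(c("train", "val", "test"), function(sub) {
        sp <- species_of_subset(file.path(split_dir, "split.csv"), sub)
        cm <- cropman[spc[cropman$image_id] %in% sp, ]
        if (nrow(cm) == 0)
          return(data.frame(subset = sub, n = 0, ACC = NA, PR = NA,
                            F1 = NA, AUC = NA))
        ids <- unique(cm$image_id)
        scores <- vapply(ids, function(id) {
          crops <- lapply(cm$crop_id[cm$image_id == id], function(cid)
            read_image_png(file.path(crops_dir, paste0(cid, ".png"))))
          predict_image(model, crops)
        }, numeric(1))
        m <- compute_metrics(scores = scores, labels = lab[ids],
                             threshold = model$cfg$threshold)
        data.frame(subset = sub, n = length(ids), ACC = m$ACC, PR = m$PR,
                   F1 = m$F1, AUC = m$AUC)
      })
      metrics <- do.call(rbind, rows)
      write.csv(metrics, file.path(root, "metrics.csv"), row.names = FALSE)
      manifests[[stage]] <- write_manifest(
        root, stage,
        inputs = c(file.path(cls_dir, "weights.rds"),
                   file.path(crops_dir, "crops.csv")),
        outputs = file.path(root, "metrics.csv"),
        seed = sseed, config = list(threshold = cfg$cls$threshold))
    } else if (stage == "robustness") {
      ph <- read_phantom_dir(phantom_dir)
      require_artifact(file.path(cls_dir, "weights.rds"))
      model <- load_model(cls_dir)
      test_sp <- species_of_subset(file.path(split_dir, "split.csv"), "test")
      test_scenes <- Filter(function(s) s$scene$species_id %in% test_sp, ph$scenes)
      if (length(test_scenes) == 0) test_scenes <- ph$scenes
      segm <- if (!cfg$use_reference_masks) load_model(seg_dir)
      sweep <- distortion_sweep(model, list(scenes = test_scenes),
                                cfg$distortion, cfg$crop,
                                segmenter = segm, tiling = cfg$tiling,
                                use_reference_masks = cfg$use_reference_masks,
                                threshold = cfg$cls$threshold)
      write.csv(sweep, file.path(root, "sweep.csv"), row.names = FALSE)
      manifests[[stage]] <- write_manifest(
        root, stage, inputs = file.path(cls_dir, "weights.rds"),
        outputs = file.path(root, "sweep.csv"),
        seed = sseed, config = cfg$distortion)
    }
  }
  invisible(manifests)
}
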