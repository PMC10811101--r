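# Species-aware dataset stratification.
#
# Image sets are grouped by wheat species (all images of a species move
# together, preventing leakage of near-identical spikes across subsamples)
# and are class-imbalanced: the hairless/haired ratio k of the full set must
# be preserved in train, validation and test. Two strategies are provided:
# an iterated randomized search minimizing the spread of k across the three
# subsamples, and a deterministic split maximizing the number of species
# represented in the training subsample.

#' Hairless-to-haired image count ratio k
#'
#' @param n_haired,n_hairless image counts.
#' @return `n_hairless / n_haired`, or `NA` (undefined-ratio flag) when
#'   `n_haired` is zero.
#' @export
compute_k <- function(n_haired, n_hairless) {
  if (n_haired == 0) return(NA_real_)
  n_hairless / n_haired
}

#' Maximum deviation of k across the three subsamples
#'
#' The spread is the maximum pairwise absolute difference
#' `max(|k_i - k_j|)`; an alternative convention, the maximum absolute
#' deviation from a global reference ratio, is available via `mode`.
#'
#' @param k_train,k_val,k_test per-subsample ratios.
#' @param mode `"pairwise"` (default) or `"global"`.
#' @param k_global reference ratio for `mode = "global"`.
#' @return The deviation, or `NA` if any input ratio is undefined.
#' @export
compute_dev <- function(k_train, k_val, k_test, mode = c("pairwise", "global"),
                        k_global = NULL) {
  mode <- match.arg(mode)
  ks <- c(k_train, k_val, k_test)
  if (anyNA(ks)) return(NA_real_)
  if (mode == "pairwise") max(abs(outer(ks, ks, "-")))
  else max(abs(ks - k_global))
}

#' Stratification configuration
#'
#' @param target_fractions named train/val/test fractions (must sum to 1).
#' @param epsilon tolerance on the val/test fractions.
#' @param max_iterations outer iteration cap of the randomized search.
#' @param dev_threshold early-stop threshold on the k spread.
#' @param dev_mode see [compute_dev()].
#' @param joint_epsilon if `TRUE`, the early-flush condition of the
#'   randomized search requires only the *sum* of val+test deviations within
#'   epsilon; default `FALSE` checks val and test individually.
#' @param seed RNG seed.
#' @return Object of class `stratify_config`.
#' @export
stratify_config <- function(target_fractions = c(train = 0.8, val = 0.1, test = 0.1),
                            epsilon = 0.01, max_iterations = 10000L,
                            dev_threshold = 0.01,
                            dev_mode = c("pairwise", "global"),
                            joint_epsilon = FALSE, seed = 1L) {
  if (abs(sum(target_fractions) - 1) > 1e-9)
    stop("target fractions must sum to 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(target_fractions = target_fractions, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 dev_threshold = dev_threshold,
                 dev_mode = match.arg(dev_mode),
                 joint_epsilon = isTRUE(joint_epsilon),
                 seed = as.integer(seed)),
            class = "stratify_config")
}

split_counts <- function(table, assignment) {
  out <- lapply(c("train", "val", "test"), function(s) {
    sel <- assignment == s
    c(n_haired = sum(table$n_haired[sel]), n_hairless = sum(table$n_hairless[sel]))
  })
  names(out) <- c("train", "val", "test")
  out
}

split_summary <- function(table, assignment, cfg) {
  cnt <- split_counts(table, assignment)
  ks <- vapply(cnt, function(x) compute_k(x[["n_haired"]], x[["n_hairless"]]),
               numeric(1))
  total_h <- sum(table$n_haired); total_n <- sum(table$n_hairless)
  dev <- compute_dev(ks[["train"]], ks[["val"]], ks[["test"]],
                     mode = cfg$dev_mode,
                     k_global = compute_k(total_h, total_n))
  list(counts = cnt, k = ks, dev = dev)
}

# One candidate assignment of the iterated randomized search.
balanced_candidate <- function(table, cfg) {
  n <- nrow(table)
  total <- sum(table$n_haired + table$n_hairless)
  sizes <- table$n_haired + table$n_hairless
  fracs <- sizes / total
  assignment <- rep(NA_character_, n)
  cap <- cfg$target_fractions[["val"]] + cfg$epsilon   # val and test share the 0.1 target
  assignment[fracs > cap] <- "train"                   # dominant species forced to train
  sub_n <- c(train = 0, val = 0, test = 0)
  sub_n["train"] <- sum(sizes[which(assignment == "train")])
  remaining <- which(is.na(assignment))
  while (length(remaining) > 0) {
    i <- if (length(remaining) == 1L) remaining else sample(remaining, 1L)
    s <- sample(c("train", "val", "test"), 1L)
    if (s == "train") {
      assignment[i] <- "train"
    } else {
      if ((sub_n[[s]] + sizes[i]) / total < cap) assignment[i] <- s
      else assignment[i] <- "train"
    }
    sub_n[[assignment[i]]] <- sub_n[[assignment[i]]] + sizes[i]
    remaining <- which(is.na(assignment))
    dv <- abs(sub_n[["val"]] / total - cfg$target_fractions[["val"]])
    dt <- abs(sub_n[["test"]] / total - cfg$target_fractions[["test"]])
    filled <- if (cfg$joint_epsilon) (dv + dt) <= 2 * cfg$epsilon
    else dv <= cfg$epsilon && dt <= cfg$epsilon
    if (filled) {
      assignment[remaining] <- "train"
      remaining <- integer(0)
    }
  }
  assignment
}

#' Randomized class-balanced stratification
#'
#' Iterated randomized search: species holding more than `0.1 + epsilon` of
#' all images are forced into train; the remaining species are assigned one
#' by one to a randomly chosen subsample, with val/test refusing additions
#' that would push them past their target fraction plus epsilon (such
#' species overflow into train); once val and test are within epsilon of
#' their targets all remaining species are flushed to train. Each candidate
#' split's k spread (`dev`) is computed and the best split is retained; the
#' search stops when `dev < dev_threshold` or after `max_iterations`
#' candidates.
#'
#' @param table an `sg_species_table` (or data.frame with `species_id`,
#'   `n_haired`, `n_hairless`).
#' @param cfg a [stratify_config()].
#' @param audit if `TRUE` (default), keep a per-iteration log of candidate
#'   devs and the running best.
#' @return Object of class `sg_split`: list with `assignment` (data.frame
#'   species_id/subsample), `counts`, `k` (per subsample), `dev`,
#'   `iterations_used`, `best_index`, `converged`, and (optionally) `audit`
#'   (data.frame iteration/dev/best_dev).
#' @export
stratify_balanced_by_class <- function(table, cfg = stratify_config(),
                                       audit = TRUE) {
  stopifnot(all(c("species_id", "n_haired", "n_hairless") %in% names(table)))
  set.seed(cfg$seed)
  total <- sum(table$n_haired + table$n_hairless)
  sizes <- table$n_haired + table$n_hairless
  if (all(sizes / total > cfg$target_fractions[["val"]] + cfg$epsilon)) {
    warning("all species forced to train; degenerate split with empty val/test",
            call. = FALSE)
    assignment <- rep("train", nrow(table))
    sm <- split_summary(table, assignment, cfg)
    return(structure(list(
      assignment = data.frame(species_id = table$species_id, subsample = assignment),
      counts = sm$counts, k = sm$k, dev = sm$dev, iterations_used = 0L,
      best_index = 0L, converged = FALSE,
      audit = if (audit) data.frame(iteration = integer(), dev = numeric(),
                                    best_dev = numeric())),
      class = "sg_split"))
  }
  best <- NULL
  best_index <- 0L
  log_rows <- vector("list", 0L)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    assignment <- balanced_candidate(table, cfg)
    sm <- split_summary(table, assignment, cfg)
    dev_eff <- if (is.na(sm$dev)) Inf else sm$dev
    if (is.null(best) || dev_eff < best$dev_eff) {
      best <- list(assignment = assignment, sm = sm, dev_eff = dev_eff)
      best_index <- iter
    }
    if (audit)
      log_rows[[iter]] <- data.frame(iteration = iter, dev = sm$dev,
                                     best_dev = best$sm$dev)
    if (dev_eff < cfg$dev_threshold) { converged <- TRUE; break }
    if (iter >= cfg$max_iterations) break
  }
  structure(list(
    assignment = data.frame(species_id = table$species_id,
                            subsample = best$assignment),
    counts = best$sm$counts, k = best$sm$k, dev = best$sm$dev,
    iterations_used = iter, best_index = best_index, converged = converged,
    audit = if (audit) do.call(rbind, log_rows)),
    class = "sg_split")
}

# All subsets of `idx` with size <= kmax, as a list of integer vectors.
subsets_upto <- function(idx, kmax) {
  out <- list(integer(0))
  for (k in seq_len(min(kmax, length(idx)))) {
    cmb <- utils::combn(idx, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Train-diversity-maximizing stratification
#'
#' Fills validation and test with as few species as possible while bringing
#' each within `epsilon` of its target fraction, so the number of distinct
#' species represented in the training subsample is maximal among splits
#' meeting the size targets. Candidate val/test species sets up to
#' `max_subset` species each are enumerated exhaustively; among feasible
#' pairs the one with the fewest val+test species wins, ties broken by
#' smaller total deviation from the target fractions, then by smaller k
#' spread. If no pair lands inside the epsilon band, the pair minimizing the
#' total deviation is returned with a warning. Deterministic.
#'
#' @param table species table (>= 3 species).
#' @param cfg a [stratify_config()].
#' @param max_subset maximum number of species per val/test subsample
#'   considered in the enumeration.
#' @return An `sg_split` (see [stratify_balanced_by_class()]).
#' @export
stratify_train_max_diversity <- function(table, cfg = stratify_config(),
                                         max_subset = 3L) {
  stopifnot(all(c("species_id", "n_haired", "n_hairless") %in% names(table)))
  n <- nrow(table)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  total <- sum(table$n_haired + table$n_hairless)
  sizes <- table$n_haired + table$n_hairless
  fracs <- sizes / total
  cap <- cfg$target_fractions[["val"]] + cfg$epsilon
  eligible <- which(fracs <= cap)      # dominant species stay in train
  cand <- subsets_upto(eligible, max_subset)
  cand <- cand[lengths(cand) > 0]
  t_val <- cfg$target_fractions[["val"]]; t_test <- cfg$target_fractions[["test"]]
  best <- NULL
  for (vi in seq_along(cand)) {
    v <- cand[[vi]]
    fv <- sum(fracs[v])
    if (fv > cap) next
    dv <- abs(fv - t_val)
    for (ti in seq_along(cand)) {
      t <- cand[[ti]]
      if (length(intersect(v, t))) next
      ft <- sum(fracs[t])
      if (ft > cap) next
      dt <- abs(ft - t_test)
      feasible <- dv <= cfg$epsilon && dt <= cfg$epsilon
      assignment <- rep("train", n)
      assignment[v] <- "val"; assignment[t] <- "test"
      sm <- split_summary(table, assignment, cfg)
      dev_eff <- if (is.na(sm$dev)) Inf else sm$dev
      key <- list(feasible = feasible, n_out = length(v) + length(t),
                  frac_dev = dv + dt, dev = dev_eff,
                  assignment = assignment, sm = sm)
      better <- is.null(best) ||
        (key$feasible && !best$feasible) ||
        (key$feasible == best$feasible && (
          key$n_out < best$n_out ||
          (key$n_out == best$n_out && (
            key$frac_dev < best$frac_dev - 1e-12 ||
            (abs(key$frac_dev - best$frac_dev) <= 1e-12 && key$dev < best$dev)))))
      if (better) best <- key
    }
  }
  if (is.null(best)) {
    warning("too few species to populate val/test; degenerate all-train split",
            call. = FALSE)
    assignment <- rep("train", n)
    sm <- split_summary(table, assignment, cfg)
    best <- list(feasible = FALSE, assignment = assignment, sm = sm)
  } else if (!best$feasible) {
    warning("no val/test species combination lands within epsilon of the ",
            "target fractions; returning the closest split", call. = FALSE)
  }
  structure(list(
    assignment = data.frame(species_id = table$species_id,
                            subsample = best$assignment),
    counts = best$sm$counts, k = best$sm$k, dev = best$sm$dev,
    iterations_used = 1L, best_index = 1L, converged = isTRUE(best$feasible),
    audit = NULL),
    class = "sg_split")
}

#' Write a split and its summary to disk
#'
#' Writes `split.csv` (species_id, subsample) and `summary.json` (per
#' subsample counts and k, dev, iterations_used, seed).
#'
#' @param split an `sg_split`.
#' @param dir output directory.
#' @param seed seed to record.
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(split$assignment, file.path(dir, "split.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = as.list(split$k), dev = split$dev,
         counts = split$counts,
         iterations_used = split$iterations_used,
         best_index = split$best_index, converged = split$converged,
         seed = seed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Aggregate a phantom metadata table into a species table
#'
#' @param metadata data.frame with `species_id` and `pubescence` columns
#'   (e.g. from [generate_dataset()]).
#' @return An `sg_species_table`.
#' @export
metadata_to_species_table <- function(metadata) {
  sp <- sort(unique(metadata$species_id))
  tab <- data.frame(
    species_id = sp,
    n_haired = vapply(sp, function(s)
      sum(metadata$pubescence[metadata$species_id == s] == 1L), integer(1)),
    n_hairless = vapply(sp, function(s)
      sum(metadata$pubescence[metadata$species_id == s] == 0L), integer(1))
  )
  rownames(tab) <- NULL
  generate_species_table(nrow(tab), tab)
}
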