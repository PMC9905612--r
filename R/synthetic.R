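# Synthetic blood-smear benchmark generator. Works purely in
# annotation/detection space (no pixel rendering): scenes are sets of
# ground-truth leukocyte boxes with class labels and interference-factor
# tags, and detectors are stochastic corruption models applied to those
# ground truths. Every output is a pure function of (configuration, seed);
# R's Mersenne-Twister generator is used with an explicit integer seed that
# is recorded into each generated bundle.

#' Scene generator configuration
#'
#' Defaults emulate the multi-cell blood-smear dataset the package targets:
#' 600x600 images (the "mini" working resolution), class frequencies
#' proportional to the dataset totals NG:BG:EG:L:M = 4135:300:1100:1879:1181,
#' a cells-per-image distribution averaging ~1.4 cells with roughly a third
#' of images multi-cell, and an 80/20 train/test split (ratio 4:1).
#'
#' @param width,height image extent in pixels.
#' @param cells_per_image_probs probabilities of an image containing
#'   0, 1, 2, ... cells (vector indexed from 0 cells).
#' @param class_probs named vector of class frequencies over [lk_classes()];
#'   normalized to sum to 1.
#' @param cell_size_mean,cell_size_sd mean and sd of the (normal, truncated)
#'   cell box side length in pixels.
#' @param cell_size_range truncation bounds for the side length.
#' @param max_gt_overlap maximum pairwise IoU allowed between placed cells
#'   (distinct leukocytes never coincide; moderate touching is allowed).
#' @param tag_probs named vector of per-image Bernoulli probabilities for the
#'   interference-factor tags of [lk_tags()]; tags are drawn independently
#'   per image and inherited by its ground truths.
#' @param split_fraction fraction of images assigned to the training split.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 600, height = 600,
                         cells_per_image_probs = c(0, 0.65, 0.25, 0.10),
                         class_probs = c(NG = 4135, BG = 300, EG = 1100,
                                         L = 1879, M = 1181),
                         cell_size_mean = 90, cell_size_sd = 15,
                         cell_size_range = c(50, 150),
                         max_gt_overlap = 0.3,
                         tag_probs = c(high_ph = 0.07, low_ph = 0.05,
                                       overlapping = 0.05, impurity = 0.05,
                                       incomplete = 0.04),
                         split_fraction = 0.8) {
  stopifnot(width > 0, height > 0,
            all(cells_per_image_probs >= 0), sum(cells_per_image_probs) > 0,
            all(class_probs >= 0), sum(class_probs) > 0,
            split_fraction > 0, split_fraction < 1,
            cell_size_range[1] > 0, cell_size_range[2] <= min(width, height))
  check_labels(names(class_probs), what = "class_probs name")
  if (length(tag_probs)) check_tags(names(tag_probs))
  cfg <- list(width = width, height = height,
              cells_per_image_probs = cells_per_image_probs / sum(cells_per_image_probs),
              class_probs = class_probs[lk_classes()] / sum(class_probs),
              cell_size_mean = cell_size_mean, cell_size_sd = cell_size_sd,
              cell_size_range = cell_size_range,
              max_gt_overlap = max_gt_overlap,
              tag_probs = tag_probs,
              split_fraction = split_fraction)
  class(cfg) <- "scene_config"
  cfg
}

#' Detector noise profile
#'
#' Describes one simulated detector: its miss (false-negative) probability,
#' false-positive rate per image, corner jitter as a fraction of box size, a
#' row-stochastic 5x5 class-confusion matrix, a confidence model linking
#' localization error to the reported score, and multipliers that modulate
#' the error rates on tagged ground truths (stain/pH tags inflate confusion,
#' overlap tags inflate misses, impurity tags inflate false positives).
#'
#' The confidence model is
#' `confidence = clamp(base - slope * (1 - IoU(jittered, true)) + noise, eps, 1)`:
#' a monotone link between localization quality and score, the minimal
#' assumption under which confidence-weighted box fusion is meaningful.
#'
#' @param miss probability a ground truth goes undetected.
#' @param fp_rate expected false positives per image (Poisson).
#' @param jitter sd of corner noise as a fraction of box width/height.
#' @param confusion 5x5 row-stochastic matrix over [lk_classes()], or a
#'   scalar off-diagonal total (e.g. `0.05` spreads 5% uniformly over the
#'   four wrong classes).
#' @param conf_base,conf_slope,conf_noise_sd,conf_floor confidence-model
#'   parameters.
#' @param fp_conf_range range of uniform confidences for false positives.
#' @param tag_multipliers named list with elements `miss`, `confusion`, `fp`,
#'   each a named vector of multiplicative factors applied when the ground
#'   truth (or image) carries the corresponding tag.
#' @return An object of class `detector_profile`.
#' @export
detector_profile <- function(miss = 0.1, fp_rate = 0.5, jitter = 0.05,
                             confusion = 0.05,
                             conf_base = 0.95, conf_slope = 1.5,
                             conf_noise_sd = 0.03, conf_floor = 0.05,
                             fp_conf_range = c(0.05, 0.6),
                             tag_multipliers = list(
                               miss = c(overlapping = 2, overlapping_cells = 2,
                                        incomplete = 1.5),
                               confusion = c(high_ph = 2, low_ph = 2,
                                             colour_cast = 1.5,
                                             degenerated_cells = 2),
                               fp = c(impurity = 2, impurities = 2))) {
  k <- length(lk_classes())
  if (is.matrix(confusion)) {
    stopifnot(nrow(confusion) == k, ncol(confusion) == k,
              all(confusion >= 0),
              all(abs(rowSums(confusion) - 1) < 1e-8))
  } else {
    stopifnot(confusion >= 0, confusion < 1)
    off <- confusion / (k - 1)
    confusion <- matrix(off, k, k)
    diag(confusion) <- 1 - confusion[1, 2] * (k - 1)
  }
  dimnames(confusion) <- list(lk_classes(), lk_classes())
  stopifnot(miss >= 0, miss <= 1, fp_rate >= 0, jitter >= 0)
  p <- list(miss = miss, fp_rate = fp_rate, jitter = jitter,
            confusion = confusion,
            conf_base = conf_base, conf_slope = conf_slope,
            conf_noise_sd = conf_noise_sd, conf_floor = conf_floor,
            fp_conf_range = fp_conf_range,
            tag_multipliers = tag_multipliers)
  class(p) <- "detector_profile"
  p
}

tag_factor <- function(mult, tags) {
  if (length(tags) == 0 || is.null(mult)) return(1)
  prod(mult[intersect(names(mult), tags)], na.rm = TRUE)
}

#' Generate one synthetic scene
#'
#' Draws a cell count, places non-coincident leukocyte boxes fully inside the
#' image, assigns class labels from the configured frequencies, and tags the
#' image (and hence its ground truths) with interference factors. Consumes
#' the current RNG state; seed at the call site for reproducibility.
#'
#' @param cfg a [scene_config()].
#' @param image_id identifier for the generated image.
#' @return List with `image_id`, `width`, `height`, `tags` (image-level) and
#'   `gts` (a ground-truth table, possibly empty).
#' @export
generate_scene <- function(cfg = scene_config(), image_id = 1L) {
  n_cells <- sample.int(length(cfg$cells_per_image_probs), 1,
                        prob = cfg$cells_per_image_probs) - 1L
  img_tags <- names(cfg$tag_probs)[stats::runif(length(cfg$tag_probs)) < cfg$tag_probs]
  boxes <- matrix(numeric(0), ncol = 4)
  placed <- 0L; attempts <- 0L
  while (placed < n_cells) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(n_cells, 1L)) {
      stop("could not place ", n_cells, " cells in a ", cfg$width, "x",
           cfg$height, " scene within the retry budget; cells too large or ",
           "overlap cap too strict", call. = FALSE)
    }
    w <- min(max(stats::rnorm(1, cfg$cell_size_mean, cfg$cell_size_sd),
                 cfg$cell_size_range[1]), cfg$cell_size_range[2])
    h <- min(max(stats::rnorm(1, cfg$cell_size_mean, cfg$cell_size_sd),
                 cfg$cell_size_range[1]), cfg$cell_size_range[2])
    x1 <- stats::runif(1, 0, cfg$width - w)
    y1 <- stats::runif(1, 0, cfg$height - h)
    cand <- c(x1, y1, x1 + w, y1 + h)
    if (placed > 0) {
      cdf <- data.frame(x1 = cand[1], y1 = cand[2], x2 = cand[3], y2 = cand[4])
      bdf <- as.data.frame(boxes); names(bdf) <- c("x1", "y1", "x2", "y2")
      if (max(iou_matrix(cdf, bdf)) > cfg$max_gt_overlap) next
    }
    boxes <- rbind(boxes, cand)
    placed <- placed + 1L
  }
  labels <- if (n_cells > 0) {
    sample(lk_classes(), n_cells, replace = TRUE, prob = cfg$class_probs)
  } else character(0)
  gts <- if (n_cells > 0) {
    ground_truths(image_id = rep(image_id, n_cells),
                  x1 = boxes[, 1], y1 = boxes[, 2],
                  x2 = boxes[, 3], y2 = boxes[, 4],
                  label = labels,
                  tags = rep(list(img_tags), n_cells))
  } else {
    g <- ground_truths(image_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                       x2 = numeric(0), y2 = numeric(0), label = character(0))
    g
  }
  list(image_id = image_id, width = cfg$width, height = cfg$height,
       tags = img_tags, gts = gts)
}

#' Simulate one detector on a scene's ground truths
#'
#' For each ground truth, with probability `1 - miss` (tag-modulated) emits a
#' detection: corners jittered by centred Gaussian noise scaled to the box
#' size, label drawn from the confusion-matrix row (off-diagonal mass
#' tag-modulated), confidence decreasing in the realized localization error.
#' Additionally emits Poisson false positives with random boxes, uniform
#' random labels and low confidences. Consumes the current RNG state.
#'
#' @param scene a scene from [generate_scene()] (uses its ground truths,
#'   extent and tags).
#' @param profile a [detector_profile()].
#' @param model_id identifier of the simulated detector.
#' @return A detection table (see [detections()]).
#' @export
simulate_detector <- function(scene, profile, model_id = "m1") {
  gts <- scene$gts
  out <- list()
  for (i in seq_len(nrow(gts))) {
    tags <- gts$tags[[i]]
    p_miss <- min(profile$miss * tag_factor(profile$tag_multipliers$miss, tags), 1)
    if (stats::runif(1) < p_miss) next
    w <- gts$x2[i] - gts$x1[i]; h <- gts$y2[i] - gts$y1[i]
    true_box <- c(gts$x1[i], gts$y1[i], gts$x2[i], gts$y2[i])
    jit <- stats::rnorm(4, 0, profile$jitter) * c(w, h, w, h)
    box <- true_box + jit
    if (box[3] <= box[1] || box[4] <= box[2]) next  # jitter collapsed the box: a miss
    box <- tryCatch(clip_box(box, scene$width, scene$height),
                    error = function(e) NULL)
    if (is.null(box)) next
    conf_row <- profile$confusion[gts$label[i], ]
    cf <- tag_factor(profile$tag_multipliers$confusion, tags)
    if (cf != 1) {
      diag_i <- gts$label[i]
      off <- conf_row; off[diag_i] <- 0
      off <- off * cf
      s <- sum(off)
      if (s >= 1) { off <- off / s * 0.99; s <- 0.99 }
      conf_row <- off; conf_row[diag_i] <- 1 - s
    }
    label <- sample(lk_classes(), 1, prob = conf_row)
    loc_err <- 1 - box_iou(box, true_box)
    conf <- profile$conf_base - profile$conf_slope * loc_err +
      stats::rnorm(1, 0, profile$conf_noise_sd)
    conf <- min(max(conf, profile$conf_floor), 1)
    out[[length(out) + 1L]] <- data.frame(
      image_id = scene$image_id, x1 = box[1], y1 = box[2],
      x2 = box[3], y2 = box[4], confidence = conf, label = label,
      model_id = model_id, stringsAsFactors = FALSE)
  }
  fp_rate <- profile$fp_rate * tag_factor(profile$tag_multipliers$fp, scene$tags)
  n_fp <- stats::rpois(1, fp_rate)
  for (k in seq_len(n_fp)) {
    w <- stats::runif(1, 30, min(120, scene$width / 2))
    h <- stats::runif(1, 30, min(120, scene$height / 2))
    x1 <- stats::runif(1, 0, scene$width - w)
    y1 <- stats::runif(1, 0, scene$height - h)
    out[[length(out) + 1L]] <- data.frame(
      image_id = scene$image_id, x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
      confidence = stats::runif(1, profile$fp_conf_range[1], profile$fp_conf_range[2]),
      label = sample(lk_classes(), 1),
      model_id = model_id, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_detections())
  do.call(rbind, out)
}

#' Generate a complete multi-detector benchmark
#'
#' Generates `n_images` scenes from one scene configuration, simulates each
#' detector profile on every scene, and assigns a deterministic train/test
#' split. The result is a self-consistent bundle: ground truths, per-model
#' detection tables, image table, split assignment, and the seed used.
#'
#' @param scene_cfg a [scene_config()].
#' @param profiles list of [detector_profile()] objects, one per simulated
#'   detector (named, or names `m1...mM` are assigned).
#' @param n_images number of scenes to generate.
#' @param seed integer seed; the bundle is a pure function of
#'   `(scene_cfg, profiles, n_images, seed)`.
#' @return List of class `benchmark_bundle` with elements `images` (data
#'   frame: image_id, width, height, split), `gts`, `detections` (named list
#'   of per-model detection tables), `image_tags` (named list), and `seed`.
#' @export
generate_benchmark <- function(scene_cfg, profiles, n_images, seed) {
  stopifnot(length(profiles) >= 1, n_images >= 1)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("m", seq_along(profiles))
  }
  set.seed(as.integer(seed))
  scenes <- lapply(seq_len(n_images), function(i) generate_scene(scene_cfg, image_id = i))
  dets <- lapply(names(profiles), function(mid) {
    per_scene <- lapply(scenes, simulate_detector,
                        profile = profiles[[mid]], model_id = mid)
    do.call(rbind, per_scene)
  })
  names(dets) <- names(profiles)
  n_train <- round(scene_cfg$split_fraction * n_images)
  split <- rep("test", n_images)
  split[sample.int(n_images, n_train)] <- "train"
  gts <- do.call(rbind, lapply(scenes, `[[`, "gts"))
  rownames(gts) <- NULL
  bundle <- list(
    images = data.frame(image_id = seq_len(n_images),
                        width = scene_cfg$width, height = scene_cfg$height,
                        split = split, stringsAsFactors = FALSE),
    gts = gts,
    detections = dets,
    image_tags = stats::setNames(lapply(scenes, `[[`, "tags"),
                                 seq_len(n_images)),
    seed = as.integer(seed))
  class(bundle) <- "benchmark_bundle"
  bundle
}

#' @export
print.benchmark_bundle <- function(x, ...) {
  cat("benchmark_bundle:", nrow(x$images), "images,", nrow(x$gts),
      "ground truths,", length(x$detections), "detector(s), seed", x$seed, "\n")
  invisible(x)
}
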