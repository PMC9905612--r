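# Random fixture generators (all consume the current RNG state; tests seed
# explicitly).

random_box <- function(extent = 100, min_side = 8, max_side = 40) {
  w <- runif(1, min_side, max_side); h <- runif(1, min_side, max_side)
  x1 <- runif(1, 0, extent - w); y1 <- runif(1, 0, extent - h)
  c(x1, y1, x1 + w, y1 + h)
}

# A random one-image multi-model detection table (clusters arise naturally
# from overlapping geometry).
random_detections <- function(n_boxes, n_models = 6, extent = 100,
                              n_anchors = max(1, n_boxes %/% 3)) {
  anchors <- lapply(seq_len(n_anchors), function(i) random_box(extent))
  rows <- lapply(seq_len(n_boxes), function(i) {
    a <- anchors[[sample.int(n_anchors, 1)]]
    jit <- rnorm(4, 0, 0.04) * rep(c(a[3] - a[1], a[4] - a[2]), 2)
    b <- a + jit
    if (b[3] <= b[1] || b[4] <= b[2]) b <- a
    data.frame(image_id = 1L, x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
               confidence = runif(1, 0.05, 1),
               label = sample(lk_classes(), 1),
               model_id = paste0("m", sample.int(n_models, 1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# A small random detection/ground-truth pair spanning a few images, suitable
# for exercising the evaluator.
random_eval_instance <- function(n_images = 6, seed_profile = NULL) {
  gt_rows <- list(); det_rows <- list()
  for (img in seq_len(n_images)) {
    n_gt <- sample(0:4, 1)
    for (j in seq_len(n_gt)) {
      b <- random_box(200, 15, 60)
      lab <- sample(lk_classes(), 1)
      gt_rows[[paste(img, j)]] <- data.frame(
        image_id = img, x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
        label = lab, stringsAsFactors = FALSE)
      if (runif(1) < 0.85) {  # detection for this gt, jittered, maybe mislabeled
        jit <- rnorm(4, 0, runif(1, 0.01, 0.12)) *
          rep(c(b[3] - b[1], b[4] - b[2]), 2)
        d <- b + jit
        if (d[3] <= d[1] || d[4] <= d[2]) d <- b
        det_rows[[paste(img, j)]] <- data.frame(
          image_id = img, x1 = d[1], y1 = d[2], x2 = d[3], y2 = d[4],
          confidence = runif(1, 0.2, 1),
          label = if (runif(1) < 0.9) lab else sample(lk_classes(), 1),
          model_id = "det", stringsAsFactors = FALSE)
      }
    }
    n_fp <- rpois(1, 0.7)
    for (k in seq_len(n_fp)) {
      b <- random_box(200, 15, 60)
      det_rows[[paste(img, "fp", k)]] <- data.frame(
        image_id = img, x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
        confidence = runif(1, 0.05, 0.6),
        label = sample(lk_classes(), 1),
        model_id = "det", stringsAsFactors = FALSE)
    }
  }
  gts <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    ground_truths(integer(0), numeric(0), numeric(0), numeric(0),
                  numeric(0), character(0))
  gts$tags <- rep(list(character(0)), nrow(gts))
  dets <- if (length(det_rows)) do.call(rbind, det_rows) else NULL
  if (is.null(dets)) {
    dets <- detections(integer(0), numeric(0), numeric(0), numeric(0),
                       numeric(0), numeric(0), character(0), character(0))
  }
  rownames(gts) <- NULL; rownames(dets) <- NULL
  list(dets = dets, gts = gts)
}
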