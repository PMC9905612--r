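# Independent reference implementations used as oracles. Deliberately
# straight-line, loop-based code with its own geometry helpers, sharing no
# internals with the package functions it checks.

ref_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  if (inter == 0) return(0)
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (area_a + area_b - inter)
}

# Straight-line reference of the full fusion pipeline for one image:
# greedy confidence-ordered clustering against the running weighted-mean box
# (one member per model), support filter at min_support * M, majority vote
# with summed-confidence tie-break, weighted box average, C' = sum(C)/D.
ref_fuse <- function(dets, n_models, cluster_iou = 0.55, min_support = 0.5,
                     divisor = "models") {
  n <- nrow(dets)
  ord <- order(-dets$confidence, as.character(dets$model_id), seq_len(n))
  cluster_of <- integer(n)
  boxes <- list(); weights <- list(); members <- list()
  for (i in ord) {
    b <- c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i])
    assigned <- FALSE
    for (k in seq_along(members)) {
      if (dets$model_id[i] %in% dets$model_id[members[[k]]]) next
      w <- dets$confidence[members[[k]]]
      mean_box <- c(0, 0, 0, 0)
      for (m in seq_along(members[[k]])) {
        j <- members[[k]][m]
        mean_box <- mean_box + w[m] * c(dets$x1[j], dets$y1[j], dets$x2[j], dets$y2[j])
      }
      mean_box <- mean_box / sum(w)
      if (ref_iou(b, mean_box) >= cluster_iou) {
        members[[k]] <- c(members[[k]], i)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) members[[length(members) + 1]] <- i
  }
  fused <- NULL
  classes <- lk_classes()
  for (k in seq_along(members)) {
    idx <- members[[k]]
    if (length(idx) < min_support * n_models) next
    labs <- dets$label[idx]; confs <- dets$confidence[idx]
    counts <- sapply(classes, function(cl) sum(labs == cl))
    top <- max(counts)
    cand <- classes[counts == top]
    if (length(cand) == 1) {
      lab <- cand
    } else {
      sums <- sapply(cand, function(cl) sum(confs[labs == cl]))
      best <- cand[sums == max(sums)]
      lab <- best[which.min(match(best, classes))]
    }
    box <- c(0, 0, 0, 0)
    for (m in seq_along(idx)) {
      box <- box + confs[m] * c(dets$x1[idx[m]], dets$y1[idx[m]],
                                dets$x2[idx[m]], dets$y2[idx[m]])
    }
    box <- box / sum(confs)
    d <- if (divisor == "models") n_models else top
    fused <- rbind(fused, data.frame(
      x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4],
      confidence = sum(confs) / d, label = lab, support = length(idx),
      stringsAsFactors = FALSE))
  }
  if (is.null(fused)) {
    fused <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                        y2 = numeric(0), confidence = numeric(0),
                        label = character(0), support = integer(0))
  }
  fused[order(-fused$confidence, seq_len(nrow(fused))), , drop = FALSE]
}

# Connected components of the IoU > 0 overlap graph (used for the
# well-separated-groups clustering check).
ref_components <- function(dets) {
  n <- nrow(dets)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      a <- c(dets$x1[i], dets$y1[i], dets$x2[i], dets$y2[i])
      b <- c(dets$x1[j], dets$y1[j], dets$x2[j], dets$y2[j])
      if (ref_iou(a, b) > 0 && comp[j] != comp[i]) {
        comp[c(i, j)] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# Independent reference detection evaluator: per-class, per-threshold greedy
# matching and explicit prefix-sweep 101-point interpolated AP.
ref_class_match <- function(dets, gts, cls, thr, max_det = Inf) {
  d <- dets[dets$label == cls, , drop = FALSE]
  g <- gts[gts$label == cls, , drop = FALSE]
  all_conf <- c(); all_tp <- c()
  for (img in unique(c(d$image_id, g$image_id))) {
    di <- d[d$image_id == img, , drop = FALSE]
    di <- di[order(-di$confidence), , drop = FALSE]
    if (is.finite(max_det) && nrow(di) > max_det) di <- di[1:max_det, , drop = FALSE]
    gi <- g[g$image_id == img, , drop = FALSE]
    used <- rep(FALSE, nrow(gi))
    for (i in seq_len(nrow(di))) {
      best <- 0; best_j <- 0
      for (j in seq_len(nrow(gi))) {
        if (used[j]) next
        v <- ref_iou(c(di$x1[i], di$y1[i], di$x2[i], di$y2[i]),
                     c(gi$x1[j], gi$y1[j], gi$x2[j], gi$y2[j]))
        if (v >= thr && v > best) { best <- v; best_j <- j }
      }
      tp <- best_j > 0
      if (tp) used[best_j] <- TRUE
      all_conf <- c(all_conf, di$confidence[i]); all_tp <- c(all_tp, tp)
    }
  }
  if (length(all_conf) == 0) return(list(tp = logical(0), n_gt = nrow(g)))
  ord <- order(-all_conf)
  list(tp = all_tp[ord], n_gt = nrow(g))
}

ref_ap <- function(dets, gts, cls, thr) {
  m <- ref_class_match(dets, gts, cls, thr)
  if (m$n_gt == 0) return(NA_real_)
  k <- length(m$tp)
  if (k == 0) return(0)
  prec <- cumsum(m$tp) / seq_len(k)
  rec <- cumsum(m$tp) / m$n_gt
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    for (i in seq_len(k)) if (rec[i] >= r && prec[i] > best) best <- prec[i]
    total <- total + best
  }
  total / 101
}

ref_map <- function(dets, gts, thresholds = seq(0.5, 0.95, 0.05)) {
  per_class <- sapply(lk_classes(), function(cl) {
    mean(sapply(thresholds, function(t) ref_ap(dets, gts, cl, t)))
  })
  mean(per_class, na.rm = TRUE)
}

ref_mar <- function(dets, gts, thresholds = seq(0.5, 0.95, 0.05), max_det = 100) {
  per_class <- sapply(lk_classes(), function(cl) {
    mean(sapply(thresholds, function(t) {
      m <- ref_class_match(dets, gts, cl, t, max_det = max_det)
      if (m$n_gt == 0) NA_real_ else sum(m$tp) / m$n_gt
    }))
  })
  mean(per_class, na.rm = TRUE)
}
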