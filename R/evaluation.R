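# Detection evaluation: greedy IoU matching, 101-point interpolated average
# precision, mAP/mAR over the IoU grid 0.50:0.95, per-class AP, PR curves,
# a 6x6 detection confusion matrix (five classes + background), and
# interference-factor-conditional accuracy.

#' IoU threshold grid for mAP/mAR
#'
#' The ten thresholds 0.50, 0.55, ..., 0.95 over which average precision and
#' recall are averaged.
#' @return Numeric vector of length 10.
#' @export
iou_thresholds <- function() seq(0.50, 0.95, by = 0.05)

# Deterministic evaluation order: descending confidence, ties by input order.
eval_order <- function(d) order(-d$confidence, seq_len(nrow(d)))

#' Match detections of one image against its ground truths
#'
#' Greedy matching in descending confidence order: each detection is paired
#' with the not-yet-matched ground truth (of the same class when
#' `class_aware`) with which it has the highest IoU at or above the
#' threshold; ties in IoU go to the lower ground-truth index, ties in
#' confidence to input order. Each ground truth is matched by at most one
#' detection and vice versa.
#'
#' @param dets detection rows for one image.
#' @param gts ground-truth rows for the same image.
#' @param iou_threshold matching threshold in (0, 1).
#' @param class_aware if `TRUE`, a detection can only match a ground truth of
#'   its own class.
#' @return List with `det_tp` (logical per detection, in input row order),
#'   `det_match` (matched gt row index or `NA`), and `gt_matched` (logical
#'   per ground truth).
#' @export
match_detections <- function(dets, gts, iou_threshold, class_aware = TRUE) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  nd <- nrow(dets); ng <- nrow(gts)
  det_tp <- logical(nd); det_match <- rep(NA_integer_, nd)
  gt_matched <- logical(ng)
  if (nd == 0 || ng == 0) {
    return(list(det_tp = det_tp, det_match = det_match, gt_matched = gt_matched))
  }
  iou <- iou_matrix(dets, gts)
  for (i in eval_order(dets)) {
    ok <- !gt_matched & iou[i, ] >= iou_threshold
    if (class_aware) ok <- ok & gts$label == dets$label[i]
    if (!any(ok)) next
    cand <- which(ok)
    j <- cand[which.max(iou[i, cand])]  # which.max takes the first max: low index wins
    det_tp[i] <- TRUE; det_match[i] <- j; gt_matched[j] <- TRUE
  }
  list(det_tp = det_tp, det_match = det_match, gt_matched = gt_matched)
}

# TP flags for all detections of one class at one threshold, pooled across
# images and globally sorted by confidence. Matching is done per image.
class_tp_flags <- function(dets, gts, cls, iou_threshold, max_detections = Inf) {
  d <- dets[dets$label == cls, , drop = FALSE]
  g <- gts[gts$label == cls, , drop = FALSE]
  if (nrow(d) && is.finite(max_detections)) {
    d <- do.call(rbind, lapply(split(d, d$image_id), function(di) {
      di[head(eval_order(di), max_detections), , drop = FALSE]
    }))
  }
  n_gt <- nrow(g)
  if (nrow(d) == 0) {
    return(list(conf = numeric(0), tp = logical(0), n_gt = n_gt))
  }
  tp <- logical(nrow(d))
  for (img in unique(d$image_id)) {
    di <- d$image_id == img
    gi <- g[g$image_id == img, , drop = FALSE]
    m <- match_detections(d[di, , drop = FALSE], gi, iou_threshold,
                          class_aware = TRUE)
    tp[di] <- m$det_tp
  }
  ord <- eval_order(d)
  list(conf = d$confidence[ord], tp = tp[ord], n_gt = n_gt)
}

#' 101-point interpolated average precision for one class at one threshold
#'
#' Precision is interpolated as the running maximum from the high-recall end,
#' then averaged over the 101-point recall grid 0.00, 0.01, ..., 1.00.
#' Undefined when the class has no ground truths (`NA`, never 0 by fiat).
#'
#' @param dets,gts detection and ground-truth tables (any number of images).
#' @param iou_threshold matching threshold.
#' @param class one of [lk_classes()].
#' @return AP in [0, 1], or `NA` if the class has no ground truths.
#' @export
average_precision <- function(dets, gts, iou_threshold, class) {
  check_labels(class)
  f <- class_tp_flags(dets, gts, class, iou_threshold)
  if (f$n_gt == 0) return(NA_real_)
  pr <- pr_points(f$tp, f$n_gt)
  mean(interp_precision_at(pr, seq(0, 1, by = 0.01)))
}

# cumulative precision/recall along the sorted detection list
pr_points <- function(tp, n_gt) {
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  list(recall = ctp / n_gt, precision = ctp / (ctp + cfp))
}

# max precision at recall >= r for each grid point (0 where unreachable)
interp_precision_at <- function(pr, grid) {
  n <- length(pr$recall)
  if (n == 0) return(rep(0, length(grid)))
  # running max of precision from the tail
  pmax_tail <- rev(cummax(rev(pr$precision)))
  vapply(grid, function(r) {
    i <- which(pr$recall >= r)
    if (length(i) == 0) 0 else pmax_tail[i[1]]
  }, numeric(1))
}

#' Precision-recall curve for one class at one IoU threshold
#'
#' @inheritParams average_precision
#' @return Data frame with columns `recall` (the 101-point grid) and
#'   `precision` (interpolated, non-increasing), plus the threshold and class
#'   as attributes-free columns for easy export.
#' @export
pr_curve <- function(dets, gts, iou_threshold, class) {
  check_labels(class)
  f <- class_tp_flags(dets, gts, class, iou_threshold)
  grid <- seq(0, 1, by = 0.01)
  prec <- if (f$n_gt == 0) rep(NA_real_, length(grid)) else {
    interp_precision_at(pr_points(f$tp, f$n_gt), grid)
  }
  data.frame(recall = grid, precision = prec,
             iou_threshold = iou_threshold, class = class,
             stringsAsFactors = FALSE)
}

#' Mean average precision over the IoU grid
#'
#' AP is computed per class at each of the ten thresholds 0.50:0.95, averaged
#' over thresholds, then over the classes that have ground truths (classes
#' with no ground truths are excluded from the mean, not counted as 0).
#'
#' @param dets,gts detection and ground-truth tables.
#' @param thresholds IoU thresholds (default [iou_thresholds()]).
#' @return List with `mAP` (mean over thresholds and defined classes),
#'   `by_threshold` (named vector of class-mean AP per threshold, giving
#'   mAP@0.50 and mAP@0.75), and `per_class` (AP averaged over thresholds,
#'   `NA` for classes with no ground truths).
#' @export
mean_ap <- function(dets, gts, thresholds = iou_thresholds()) {
  classes <- lk_classes()
  ap <- sapply(thresholds, function(t) {
    vapply(classes, function(cl) average_precision(dets, gts, t, cl), numeric(1))
  })  # classes x thresholds
  ap <- matrix(ap, nrow = length(classes),
               dimnames = list(classes, sprintf("%.2f", thresholds)))
  per_class <- rowMeans(ap)
  by_threshold <- colMeans(ap, na.rm = TRUE)
  by_threshold[colSums(!is.na(ap)) == 0] <- NA_real_
  list(mAP = mean(per_class, na.rm = TRUE),
       by_threshold = by_threshold,
       per_class = per_class,
       ap_matrix = ap)
}

#' Mean average recall over the IoU grid
#'
#' Recall per class and threshold is the fraction of ground truths matched,
#' using at most `max_detections` top-confidence detections per image and
#' class; it is averaged over thresholds, then over classes with ground
#' truths.
#'
#' @inheritParams mean_ap
#' @param max_detections cap on detections considered per image and class
#'   (default 100, the COCO convention).
#' @return List with `mAR` and `per_class` recall averaged over thresholds.
#' @export
mean_ar <- function(dets, gts, thresholds = iou_thresholds(),
                    max_detections = 100) {
  classes <- lk_classes()
  rec <- sapply(thresholds, function(t) {
    vapply(classes, function(cl) {
      f <- class_tp_flags(dets, gts, cl, t, max_detections = max_detections)
      if (f$n_gt == 0) NA_real_ else sum(f$tp) / f$n_gt
    }, numeric(1))
  })
  rec <- matrix(rec, nrow = length(classes), dimnames = list(classes, NULL))
  per_class <- rowMeans(rec)
  list(mAR = mean(per_class, na.rm = TRUE), per_class = per_class)
}

#' Detection confusion matrix
#'
#' Class-agnostic greedy IoU matching (so cross-class confusions are
#' observable): each matched detection/ground-truth pair increments the cell
#' (true class, predicted class); unmatched ground truths count as (true
#' class, background); unmatched detections as (background, predicted class).
#'
#' @param dets,gts detection and ground-truth tables.
#' @param iou_threshold matching threshold (default 0.5).
#' @return 6x6 integer matrix, rows = true class (+ background), columns =
#'   predicted class (+ background).
#' @export
confusion_matrix <- function(dets, gts, iou_threshold = 0.5) {
  lv <- c(lk_classes(), "background")
  cm <- matrix(0L, length(lv), length(lv), dimnames = list(truth = lv, prediction = lv))
  for (img in union(unique(dets$image_id), unique(gts$image_id))) {
    d <- dets[dets$image_id == img, , drop = FALSE]
    g <- gts[gts$image_id == img, , drop = FALSE]
    m <- match_detections(d, g, iou_threshold, class_aware = FALSE)
    for (i in seq_len(nrow(d))) {
      if (m$det_tp[i]) {
        cm[g$label[m$det_match[i]], d$label[i]] <- cm[g$label[m$det_match[i]], d$label[i]] + 1L
      } else {
        cm["background", d$label[i]] <- cm["background", d$label[i]] + 1L
      }
    }
    missed <- which(!m$gt_matched)
    for (j in missed) {
      cm[g$label[j], "background"] <- cm[g$label[j], "background"] + 1L
    }
  }
  cm
}

#' Accuracy on ground truths carrying an interference-factor tag
#'
#' Over the ground truths tagged with the given factor: the fraction matched
#' by a detection of the correct class at IoU at or above the threshold
#' (class-aware matching is run on the full image, then restricted to the
#' tagged subset). Undefined (`NA`) when no ground truth carries the tag.
#'
#' @param dets,gts detection and ground-truth tables (`gts` must carry a
#'   `tags` list-column).
#' @param tag one of [lk_tags()].
#' @param iou_threshold matching threshold (default 0.5).
#' @return Fraction in [0, 1], or `NA` if the tag is absent from `gts`.
#' @export
tagged_accuracy <- function(dets, gts, tag, iou_threshold = 0.5) {
  check_tags(tag)
  gts <- validate_ground_truths(gts)
  has_tag <- vapply(gts$tags, function(t) tag %in% t, logical(1))
  if (!any(has_tag)) return(NA_real_)
  matched <- logical(nrow(gts))
  for (img in unique(gts$image_id[has_tag])) {
    gi <- gts$image_id == img
    d <- dets[dets$image_id == img, , drop = FALSE]
    m <- match_detections(d, gts[gi, , drop = FALSE], iou_threshold,
                          class_aware = TRUE)
    matched[gi] <- m$gt_matched
  }
  sum(matched & has_tag) / sum(has_tag)
}

#' Full evaluation report
#'
#' Bundles mAP@0.50:0.95, mAP@0.50, mAP@0.75, mAR@0.50:0.95, per-class AP,
#' the detection confusion matrix, and per-tag accuracies into one object,
#' mirroring the columns of a standard detection results table.
#'
#' @param dets,gts detection and ground-truth tables.
#' @param tags tags to compute conditional accuracies for (default: every tag
#'   present in `gts`).
#' @return An object of class `eval_report`: a list with elements `mAP`,
#'   `mAP50`, `mAP75`, `mAR`, `per_class_ap`, `confusion`, `tag_accuracy`.
#' @export
evaluate_detections <- function(dets, gts, tags = NULL) {
  if (is.null(dets$model_id)) dets$model_id <- "ensemble"
  dets <- validate_detections(dets)
  gts <- validate_ground_truths(gts)
  if (is.null(tags)) tags <- sort(unique(unlist(gts$tags)))
  ap <- mean_ap(dets, gts)
  ar <- mean_ar(dets, gts)
  tag_acc <- vapply(tags, function(t) tagged_accuracy(dets, gts, t), numeric(1))
  rep <- list(mAP = ap$mAP,
              mAP50 = unname(ap$by_threshold["0.50"]),
              mAP75 = unname(ap$by_threshold["0.75"]),
              mAR = ar$mAR,
              per_class_ap = ap$per_class,
              confusion = confusion_matrix(dets, gts),
              tag_accuracy = tag_acc)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Detection evaluation report\n")
  cat(sprintf("  mAP@0.50:0.95 %.4f | mAP@0.50 %.4f | mAP@0.75 %.4f | mAR %.4f\n",
              x$mAP, x$mAP50, x$mAP75, x$mAR))
  cat("  per-class AP:",
      paste(sprintf("%s=%.4f", names(x$per_class_ap), x$per_class_ap),
            collapse = " "), "\n")
  if (length(x$tag_accuracy)) {
    cat("  tag accuracy:",
        paste(sprintf("%s=%.4f", names(x$tag_accuracy), x$tag_accuracy),
              collapse = " "), "\n")
  }
  invisible(x)
}
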