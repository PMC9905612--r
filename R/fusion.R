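# Ensemble fusion of multi-detector outputs: greedy IoU clustering of
# cross-model detections, a majority-support discard rule (clusters backed by
# fewer than half the models are dropped), majority-vote typing, and
# confidence-weighted averaging of the member boxes. Deterministic throughout:
# identical inputs yield bit-identical outputs.

#' Fusion configuration
#'
#' Collects the tunable constants of the ensemble scheme.
#'
#' @param cluster_iou IoU threshold above which a detection counts as
#'   overlapping a cluster's running fused box (default 0.55, the
#'   weighted-boxes-fusion convention).
#' @param min_support minimum cluster size as a fraction of the model count
#'   `M`; clusters with `N < min_support * M` are discarded (default 0.5:
#'   strictly fewer than half the models). A cluster at exactly the boundary
#'   is kept.
#' @param divisor denominator of the updated confidence
#'   `C' = sum(C_i) / D`: `"models"` divides by the total model count `M`, so
#'   that models that emitted no detection for the region lower the fused
#'   confidence (abstention penalty); `"majority"` divides by the majority
#'   count `T`, the literal printed form of the update. Default `"models"`.
#' @param scope which members enter the weighted box average:
#'   `"all_members"` (every overlapping detection, the printed summation) or
#'   `"majority_only"` (only members carrying the voted label).
#' @param tie_break how majority-vote ties between labels are resolved:
#'   `"summed_confidence"` (label with the larger summed confidence wins;
#'   residual ties fall back to canonical class index) or `"class_index"`.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(cluster_iou = 0.55,
                          min_support = 0.5,
                          divisor = c("models", "majority"),
                          scope = c("all_members", "majority_only"),
                          tie_break = c("summed_confidence", "class_index")) {
  stopifnot(cluster_iou > 0, cluster_iou < 1,
            min_support > 0, min_support <= 1)
  cfg <- list(cluster_iou = cluster_iou,
              min_support = min_support,
              divisor = match.arg(divisor),
              scope = match.arg(scope),
              tie_break = match.arg(tie_break))
  class(cfg) <- "fusion_config"
  cfg
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("fusion_config: cluster_iou =", x$cluster_iou,
      "| min_support =", x$min_support,
      "| divisor =", x$divisor,
      "| scope =", x$scope,
      "| tie_break =", x$tie_break, "\n")
  invisible(x)
}

# Deterministic processing order: descending confidence, ties by model_id
# then by input row order.
fusion_order <- function(d) {
  order(-d$confidence, as.character(d$model_id), seq_len(nrow(d)))
}

#' Cluster the detections of one image across models
#'
#' Greedy clustering: detections are visited in descending confidence order
#' (ties broken by model id, then input order). Each detection joins the
#' first existing cluster whose current confidence-weighted mean box overlaps
#' it with IoU at or above `cfg$cluster_iou` and which does not yet contain a
#' member from the same model; otherwise it seeds a new cluster. A model thus
#' contributes at most one member per cluster, which is what makes the
#' majority count and the support rule counts of models.
#'
#' @param dets detection table for a single image (see [detections()]).
#' @param cfg a [fusion_config()].
#' @return List of clusters; each cluster is a list with elements `members`
#'   (the member rows of `dets`) and `fused_box` (the running
#'   confidence-weighted mean of the member corners).
#' @export
cluster_detections <- function(dets, cfg = fusion_config()) {
  dets <- validate_detections(dets)
  if (nrow(dets) == 0) return(list())
  if (length(unique(dets$image_id)) > 1) {
    stop("cluster_detections expects detections from a single image", call. = FALSE)
  }
  ord <- fusion_order(dets)
  clusters <- list()
  for (i in ord) {
    det <- dets[i, , drop = FALSE]
    box <- c(det$x1, det$y1, det$x2, det$y2)
    joined <- FALSE
    for (k in seq_along(clusters)) {
      cl <- clusters[[k]]
      if (det$model_id %in% cl$members$model_id) next
      if (box_iou(box, cl$fused_box) >= cfg$cluster_iou) {
        cl$members <- rbind(cl$members, det)
        cl$fused_box <- weighted_mean_box(cl$members)
        clusters[[k]] <- cl
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1L]] <- list(members = det, fused_box = box)
    }
  }
  clusters
}

weighted_mean_box <- function(members) {
  w <- members$confidence
  sw <- sum(w)
  if (sw <= 0) stop("all member confidences are zero: weighted box undefined",
                    call. = FALSE)
  c(sum(w * members$x1), sum(w * members$y1),
    sum(w * members$x2), sum(w * members$y2)) / sw
}

#' Apply the majority-support discard rule
#'
#' A cluster of `N` overlapping detections is kept only if `N` is at least
#' `min_support * M`, where `M` is the number of models in the ensemble;
#' clusters with strictly fewer members are discarded as likely false
#' positives. Discarded members are returned, never silently dropped.
#'
#' @param clusters output of [cluster_detections()].
#' @param n_models total number of models `M` in the ensemble.
#' @param cfg a [fusion_config()].
#' @return List with elements `kept` (clusters passing the rule) and
#'   `discarded` (a detection table of all members of discarded clusters).
#' @export
filter_clusters <- function(clusters, n_models, cfg = fusion_config()) {
  stopifnot(n_models >= 1)
  sizes <- vapply(clusters, function(cl) nrow(cl$members), integer(1))
  keep <- sizes >= cfg$min_support * n_models
  discarded <- if (any(!keep)) {
    do.call(rbind, lapply(clusters[!keep], `[[`, "members"))
  } else {
    empty_detections()
  }
  list(kept = clusters[keep], discarded = discarded)
}

empty_detections <- function() {
  data.frame(image_id = character(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0), confidence = numeric(0),
             label = character(0), model_id = character(0),
             stringsAsFactors = FALSE)
}

#' Majority vote on a cluster's class label
#'
#' The fused label is the most frequent member label; `T` is its count. Ties
#' are resolved by the configured rule (`summed_confidence` by default, with
#' canonical class index as the residual tie-break) and flagged.
#'
#' @param cluster a single cluster from [cluster_detections()].
#' @param cfg a [fusion_config()].
#' @return List with `label`, `majority` (the count `T`) and `tie_broken`.
#' @export
vote_type <- function(cluster, cfg = fusion_config()) {
  members <- cluster$members
  stopifnot(nrow(members) >= 1)
  counts <- table(factor(members$label, levels = lk_classes()))
  top <- max(counts)
  contenders <- names(counts)[counts == top]
  tie <- length(contenders) > 1
  if (!tie) {
    label <- contenders
  } else if (cfg$tie_break == "summed_confidence") {
    sums <- vapply(contenders, function(lb) {
      sum(members$confidence[members$label == lb])
    }, numeric(1))
    best <- contenders[sums == max(sums)]
    # residual tie: lowest canonical class index
    label <- lk_classes()[min(match(best, lk_classes()))]
  } else {
    label <- lk_classes()[min(match(contenders, lk_classes()))]
  }
  list(label = label, majority = as.integer(top), tie_broken = tie)
}

#' Fuse one cluster into a single detection
#'
#' The fused box is the confidence-weighted mean of the member corner vectors
#' (over all members, or over majority-label members only, per
#' `cfg$scope`). The fused confidence is the summed member confidence divided
#' by the model count `M` (`divisor = "models"`: abstaining models lower the
#' result) or by the majority count `T` (`divisor = "majority"`, the literal
#' printed update, which can exceed 1 when minority-label confidences are
#' included -- the value is reported as computed, never clipped).
#'
#' @param cluster a cluster that has passed [filter_clusters()].
#' @param n_models total number of models `M`.
#' @param cfg a [fusion_config()].
#' @return One-row data frame with columns `image_id, x1, y1, x2, y2,
#'   confidence, label, support, majority, tie_broken`.
#' @export
fuse_cluster <- function(cluster, n_models, cfg = fusion_config()) {
  members <- cluster$members
  vote <- vote_type(cluster, cfg)
  scope_members <- if (cfg$scope == "majority_only") {
    members[members$label == vote$label, , drop = FALSE]
  } else members
  box <- weighted_mean_box(scope_members)
  csum <- sum(members$confidence)
  if (csum <= 0) stop("all member confidences are zero: fused confidence undefined",
                      call. = FALSE)
  divisor <- if (cfg$divisor == "models") n_models else vote$majority
  data.frame(image_id = members$image_id[1],
             x1 = box[1], y1 = box[2], x2 = box[3], y2 = box[4],
             confidence = csum / divisor,
             label = vote$label,
             support = nrow(members),
             majority = vote$majority,
             tie_broken = vote$tie_broken,
             stringsAsFactors = FALSE)
}

#' Run the full ensemble scheme on one image
#'
#' Composition of [cluster_detections()], [filter_clusters()], [vote_type()]
#' and [fuse_cluster()]: cluster the cross-model detections, discard clusters
#' supported by fewer than half the models, vote the class of each surviving
#' cluster, and average its boxes with the confidences as weights. Fused
#' detections are returned sorted by descending confidence, together with the
#' discarded detections.
#'
#' @param dets detection table for one image, pooled across models.
#' @param n_models total number of models `M` in the ensemble (not inferable
#'   from `dets`: a model that detected nothing still counts).
#' @param cfg a [fusion_config()].
#' @return List with `fused` (data frame of fused detections) and `discarded`
#'   (detection table of members of discarded clusters).
#' @export
ensemble_image <- function(dets, n_models, cfg = fusion_config()) {
  clusters <- cluster_detections(dets, cfg)
  flt <- filter_clusters(clusters, n_models, cfg)
  fused <- if (length(flt$kept)) {
    do.call(rbind, lapply(flt$kept, fuse_cluster, n_models = n_models, cfg = cfg))
  } else {
    f <- empty_detections()
    f$model_id <- NULL
    f$support <- integer(0); f$majority <- integer(0); f$tie_broken <- logical(0)
    f
  }
  ord <- order(-fused$confidence, seq_len(nrow(fused)))
  list(fused = fused[ord, , drop = FALSE], discarded = flt$discarded)
}

#' Run the ensemble scheme over a multi-image detection table
#'
#' Splits the pooled detection table by image, applies [ensemble_image()] to
#' each, and recombines the results.
#'
#' @inheritParams ensemble_image
#' @return List with `fused` and `discarded` data frames spanning all images.
#' @export
ensemble_fuse <- function(dets, n_models, cfg = fusion_config()) {
  dets <- validate_detections(dets)
  if (nrow(dets) == 0) {
    return(ensemble_image(dets, n_models, cfg))
  }
  parts <- lapply(split(dets, dets$image_id), ensemble_image,
                  n_models = n_models, cfg = cfg)
  fused <- do.call(rbind, lapply(parts, `[[`, "fused"))
  discarded <- do.call(rbind, lapply(parts, `[[`, "discarded"))
  rownames(fused) <- NULL; rownames(discarded) <- NULL
  list(fused = fused, discarded = discarded)
}
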