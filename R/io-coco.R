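# COCO-format readers and writers. Annotations use the standard layout
# (images / annotations / categories with [x, y, w, h] boxes); detector
# output uses the flat results array ({image_id, category_id, bbox, score}).
# Readers validate and reject malformed records with the offending record's
# identifier; they never repair silently. The category-id <-> class-label
# mapping is explicit configuration, never inferred from name order.

#' Default category mapping
#'
#' Bijection between COCO category ids and the five leukocyte class codes,
#' ids 1..5 in canonical class order. Pass a different named vector
#' (names = ids as strings, values = class codes) to the readers/writers if
#' an annotation file uses other ids.
#'
#' @return Named character vector mapping id -> class code.
#' @export
default_category_map <- function() {
  stats::setNames(lk_classes(), as.character(seq_along(lk_classes())))
}

# jsonlite may simplify a bbox list-of-4-vectors to a matrix or keep a list
as_bbox_matrix <- function(b) {
  m <- if (is.matrix(b)) b else do.call(rbind, b)
  if (ncol(m) != 4) stop("bbox entries must have 4 elements", call. = FALSE)
  m
}

check_category_map <- function(map) {
  if (is.null(names(map)) || anyDuplicated(names(map)) || anyDuplicated(map) ||
      !setequal(map, lk_classes())) {
    stop("category map must be a bijection from ids onto the five class codes",
         call. = FALSE)
  }
  map
}

#' Read COCO annotations
#'
#' Parses a COCO annotation JSON into the package's ground-truth and image
#' tables. Boxes are converted from `[x, y, w, h]` to corner coordinates;
#' zero-area annotations, dangling image ids and unknown category ids are
#' rejected with the offending record named.
#'
#' @param path annotation JSON file.
#' @param category_map named vector mapping category id (as character) to
#'   class code; default [default_category_map()].
#' @param tags_path optional JSON sidecar mapping image id to a vector of
#'   interference-factor tags, applied to each image's ground truths.
#' @return List with `gts` (ground-truth table) and `images` (data frame
#'   with image_id, width, height).
#' @export
read_coco_annotations <- function(path, category_map = default_category_map(),
                                  tags_path = NULL) {
  category_map <- check_category_map(category_map)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(j[[key]])) stop("COCO file lacks '", key, "' key", call. = FALSE)
  }
  images <- data.frame(image_id = j$images$id,
                       width = j$images$width, height = j$images$height,
                       stringsAsFactors = FALSE)
  ann <- j$annotations
  if (is.null(ann) || length(ann) == 0 || NROW(ann) == 0) {
    return(list(gts = validate_ground_truths(
      ground_truths(integer(0), numeric(0), numeric(0), numeric(0),
                    numeric(0), character(0))), images = images))
  }
  bbox <- as_bbox_matrix(ann$bbox)
  bad <- which(bbox[, 3] <= 0 | bbox[, 4] <= 0)
  if (length(bad)) {
    stop("annotation id ", ann$id[bad[1]], ": zero-area bbox [",
         paste(bbox[bad[1], ], collapse = ", "), "]", call. = FALSE)
  }
  dangling <- !(ann$image_id %in% images$image_id)
  if (any(dangling)) {
    stop("annotation id ", ann$id[which(dangling)[1]],
         ": image_id ", ann$image_id[which(dangling)[1]],
         " not in the image table", call. = FALSE)
  }
  lbl <- category_map[as.character(ann$category_id)]
  if (any(is.na(lbl))) {
    i <- which(is.na(lbl))[1]
    stop("annotation id ", ann$id[i], ": unknown category_id ",
         ann$category_id[i], call. = FALSE)
  }
  tags <- rep(list(character(0)), nrow(ann))
  if (!is.null(tags_path)) {
    side <- jsonlite::fromJSON(tags_path, simplifyVector = TRUE)
    tags <- lapply(as.character(ann$image_id), function(id) {
      t <- side[[id]]
      if (is.null(t)) character(0) else check_tags(as.character(t))
    })
  }
  gts <- ground_truths(image_id = ann$image_id,
                       x1 = bbox[, 1], y1 = bbox[, 2],
                       x2 = bbox[, 1] + bbox[, 3], y2 = bbox[, 2] + bbox[, 4],
                       label = unname(lbl), tags = tags)
  list(gts = gts, images = images)
}

#' Read a COCO results file as a detection table
#'
#' @param path JSON array of `{image_id, category_id, bbox, score}` records.
#' @param model_id identifier to assign to every detection read.
#' @param category_map as in [read_coco_annotations()].
#' @return A detection table (see [detections()]).
#' @export
read_coco_results <- function(path, model_id,
                              category_map = default_category_map()) {
  category_map <- check_category_map(category_map)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j) || NROW(j) == 0) return(empty_detections())
  for (key in c("image_id", "category_id", "bbox", "score")) {
    if (is.null(j[[key]])) stop("results file lacks '", key, "' field", call. = FALSE)
  }
  if (any(j$score < 0 | j$score > 1)) {
    i <- which(j$score < 0 | j$score > 1)[1]
    stop("result record ", i, ": score ", j$score[i], " outside [0, 1]",
         call. = FALSE)
  }
  lbl <- category_map[as.character(j$category_id)]
  if (any(is.na(lbl))) {
    i <- which(is.na(lbl))[1]
    stop("result record ", i, ": unknown category_id ", j$category_id[i],
         call. = FALSE)
  }
  bbox <- as_bbox_matrix(j$bbox)
  detections(image_id = j$image_id,
             x1 = bbox[, 1], y1 = bbox[, 2],
             x2 = bbox[, 1] + bbox[, 3], y2 = bbox[, 2] + bbox[, 4],
             confidence = j$score, label = unname(lbl), model_id = model_id)
}

label_to_id <- function(labels, category_map) {
  ids <- names(category_map)[match(labels, category_map)]
  as.integer(ids)
}

#' Write COCO annotations (and optional tag sidecar)
#'
#' @param gts ground-truth table.
#' @param images image table (image_id, width, height).
#' @param path output JSON path.
#' @param category_map as in [read_coco_annotations()].
#' @param tags_path if non-NULL, image-level tags (union of each image's
#'   ground-truth tags) are written to this sidecar JSON.
#' @export
write_coco_annotations <- function(gts, images, path,
                                   category_map = default_category_map(),
                                   tags_path = NULL) {
  category_map <- check_category_map(category_map)
  gts <- validate_ground_truths(gts)
  obj <- list(
    images = data.frame(id = images$image_id, width = images$width,
                        height = images$height,
                        file_name = paste0(images$image_id, ".jpg")),
    annotations = data.frame(
      id = seq_len(nrow(gts)),
      image_id = gts$image_id,
      category_id = label_to_id(gts$label, category_map),
      area = (gts$x2 - gts$x1) * (gts$y2 - gts$y1),
      iscrowd = 0L),
    categories = data.frame(id = as.integer(names(category_map)),
                            name = unname(category_map)))
  obj$annotations$bbox <- lapply(seq_len(nrow(gts)), function(i) {
    c(gts$x1[i], gts$y1[i], gts$x2[i] - gts$x1[i], gts$y2[i] - gts$y1[i])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(tags_path)) {
    per_image <- lapply(split(gts$tags, gts$image_id),
                        function(t) sort(unique(unlist(t))))
    jsonlite::write_json(per_image, tags_path, digits = NA)
  }
  invisible(path)
}

#' Write a detection table as a COCO results file
#'
#' @param dets detection table.
#' @param path output JSON path.
#' @param category_map as in [read_coco_annotations()].
#' @export
write_coco_results <- function(dets, path,
                               category_map = default_category_map()) {
  category_map <- check_category_map(category_map)
  dets <- validate_detections(dets)
  recs <- lapply(seq_len(nrow(dets)), function(i) {
    list(image_id = dets$image_id[i],
         category_id = label_to_id(dets$label[i], category_map),
         bbox = c(dets$x1[i], dets$y1[i],
                  dets$x2[i] - dets$x1[i], dets$y2[i] - dets$y1[i]),
         score = dets$confidence[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a benchmark bundle to disk in COCO formats
#'
#' Emits the annotation JSON, one results JSON per simulated detector, the
#' tag sidecar, and a small manifest recording the seed and the split.
#'
#' @param bundle a [generate_benchmark()] bundle.
#' @param dir output directory (created if missing).
#' @param category_map as in [read_coco_annotations()].
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(bundle, dir, category_map = default_category_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_coco_annotations(bundle$gts, bundle$images,
                         file.path(dir, "annotations.json"), category_map,
                         tags_path = file.path(dir, "tags.json"))
  for (mid in names(bundle$detections)) {
    write_coco_results(bundle$detections[[mid]],
                       file.path(dir, paste0("results_", mid, ".json")),
                       category_map)
  }
  jsonlite::write_json(
    list(seed = bundle$seed,
         split = stats::setNames(as.list(bundle$images$split),
                                 bundle$images$image_id)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
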