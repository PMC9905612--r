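#' Leukocyte class labels
#'
#' The five peripheral-blood white-cell types handled by the package, in
#' canonical index order: neutrophil (NG), basophil (BG), eosinophil (EG),
#' lymphocyte (L) and monocyte (M). All label columns throughout the package
#' are validated against this closed set; the order defines the class index
#' used for deterministic tie-breaking and for confusion-matrix layout.
#'
#' @return Character vector of the five canonical class codes.
#' @export
#' @examples
#' lk_classes()
lk_classes <- function() {
  c("NG", "BG", "EG", "L", "M")
}

#' Interference-factor tag vocabulary
#'
#' Closed vocabulary of condition tags that can be attached to ground-truth
#' annotations: nine clinical image-quality factors (colour cast, low
#' illumination, giant platelets, wrong focus, impurities, overlapping cells,
#' degenerated cells, and stain-buffer pH too high or too low) plus three
#' object-level conditions (overlapping, incomplete, impurity) used by the
#' subset-accuracy analyses. Unknown tags are rejected at parse time.
#'
#' @return Character vector of valid tag names.
#' @export
lk_tags <- function() {
  c("colour_cast", "low_illumination", "giant_platelets", "wrong_focus",
    "impurities", "overlapping_cells", "degenerated_cells",
    "high_ph", "low_ph",
    "overlapping", "incomplete", "impurity")
}

#' Map free-text class names to canonical codes
#'
#' Accepts the canonical two-letter codes as well as the full names commonly
#' found in VOC annotation files ("neutrophil", "basophil", ...), case
#' insensitively.
#'
#' @param x character vector of class names or codes.
#' @return Character vector of canonical codes.
#' @export
lk_normalize_label <- function(x) {
  aliases <- c(
    ng = "NG", neutrophil = "NG", `neutrophil granulocyte` = "NG",
    bg = "BG", basophil = "BG", `basophil granulocyte` = "BG",
    eg = "EG", eosinophil = "EG", `eosinophil granulocyte` = "EG",
    l = "L", lymphocyte = "L",
    m = "M", monocyte = "M"
  )
  out <- unname(aliases[tolower(x)])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown class label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out
}

check_labels <- function(labels, what = "label") {
  bad <- !(labels %in% lk_classes())
  if (any(bad)) {
    stop("invalid ", what, ": ", paste(unique(labels[bad]), collapse = ", "),
         "; must be one of ", paste(lk_classes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

check_tags <- function(tags) {
  bad <- !(tags %in% lk_tags())
  if (any(bad)) {
    stop("unknown interference-factor tag(s): ",
         paste(unique(tags[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(tags)
}

#' Construct a detection table
#'
#' Canonical in-memory container for detector output: one row per predicted
#' box, with corner coordinates, a confidence in [0, 1], a class label and the
#' identifier of the source model. All fusion and evaluation entry points
#' accept this shape.
#'
#' @param image_id vector of image identifiers.
#' @param x1,y1,x2,y2 box corner coordinates (top-left, bottom-right; may be
#'   fractional).
#' @param confidence detector confidence scores in [0, 1].
#' @param label class labels among [lk_classes()].
#' @param model_id identifier(s) of the source detector.
#' @return A `data.frame` with the canonical detection columns.
#' @export
detections <- function(image_id, x1, y1, x2, y2, confidence, label, model_id) {
  d <- data.frame(image_id = image_id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  confidence = as.numeric(confidence),
                  label = as.character(label),
                  model_id = model_id,
                  stringsAsFactors = FALSE)
  validate_detections(d)
}

validate_detections <- function(d) {
  stopifnot(is.data.frame(d))
  needed <- c("image_id", "x1", "y1", "x2", "y2", "confidence", "label", "model_id")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("detection table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d)) {
    check_boxes(d, what = "detection")
    if (any(!is.finite(d$confidence)) || any(d$confidence < 0) || any(d$confidence > 1)) {
      bad <- which(!is.finite(d$confidence) | d$confidence < 0 | d$confidence > 1)[1]
      stop("detection row ", bad, ": confidence ", d$confidence[bad],
           " outside [0, 1]", call. = FALSE)
    }
    check_labels(d$label)
  }
  d
}

#' Construct a ground-truth annotation table
#'
#' One row per annotated leukocyte: corner box, true class, the image it
#' belongs to, and an optional set of interference-factor tags (a list-column
#' of character vectors drawn from [lk_tags()]).
#'
#' @param image_id vector of image identifiers.
#' @param x1,y1,x2,y2 box corner coordinates.
#' @param label true class labels among [lk_classes()].
#' @param tags optional list of character vectors of condition tags, one per
#'   annotation; defaults to no tags.
#' @return A `data.frame` with the canonical ground-truth columns.
#' @export
ground_truths <- function(image_id, x1, y1, x2, y2, label, tags = NULL) {
  n <- length(x1)
  if (is.null(tags)) tags <- rep(list(character(0)), n)
  stopifnot(length(tags) == n)
  g <- data.frame(image_id = image_id, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  label = as.character(label), stringsAsFactors = FALSE)
  g$tags <- tags
  validate_ground_truths(g)
}

validate_ground_truths <- function(g) {
  stopifnot(is.data.frame(g))
  needed <- c("image_id", "x1", "y1", "x2", "y2", "label")
  missing <- setdiff(needed, names(g))
  if (length(missing)) {
    stop("ground-truth table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(g$tags)) g$tags <- rep(list(character(0)), nrow(g))
  if (nrow(g)) {
    check_boxes(g, what = "ground truth")
    check_labels(g$label)
    check_tags(unlist(g$tags))
  }
  g
}
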