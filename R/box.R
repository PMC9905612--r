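# Box geometry. Boxes are axis-aligned rectangles [x1, y1, x2, y2] in
# continuous, zero-based pixel coordinates (origin top-left, y downward).
# Area is (x2 - x1) * (y2 - y1), with no +1 pixel correction, so the geometry
# is invariant under uniform rescaling -- a property the weighted-average
# fusion relies on. Zero-area boxes are rejected, never repaired.

check_boxes <- function(b, what = "box") {
  co <- c("x1", "y1", "x2", "y2")
  m <- as.matrix(b[co])
  if (any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)[1]
    stop(what, " row ", bad, ": non-finite coordinate", call. = FALSE)
  }
  bad <- which(b$x2 <= b$x1 | b$y2 <= b$y1)
  if (length(bad)) {
    i <- bad[1]
    field <- if (b$x2[i] <= b$x1[i]) "x2 <= x1" else "y2 <= y1"
    stop(what, " row ", i, ": degenerate box (", field, "): [",
         paste(signif(m[i, ], 6), collapse = ", "), "]", call. = FALSE)
  }
  invisible(b)
}

box_area <- function(x1, y1, x2, y2) (x2 - x1) * (y2 - y1)

#' Intersection over union of two boxes
#'
#' @param a,b numeric vectors `c(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`.
#' @return IoU in [0, 1]; 0 for disjoint boxes.
#' @export
#' @examples
#' box_iou(c(0, 0, 10, 10), c(0, 5, 10, 15))  # 1/3
box_iou <- function(a, b) {
  a <- unname(as.numeric(a)); b <- unname(as.numeric(b))
  check_boxes(data.frame(x1 = a[1], y1 = a[2], x2 = a[3], y2 = a[4]))
  check_boxes(data.frame(x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4]))
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- box_area(a[1], a[2], a[3], a[4]) + box_area(b[1], b[2], b[3], b[4]) - inter
  inter / union
}

#' Pairwise IoU matrix between two sets of boxes
#'
#' @param a,b data frames (or matrices with named columns) carrying columns
#'   `x1, y1, x2, y2`; rows are boxes.
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(numeric(0), nrow = na, ncol = nb))
  check_boxes(a); check_boxes(b)
  ix1 <- outer(a$x1, b$x1, pmax); iy1 <- outer(a$y1, b$y1, pmax)
  ix2 <- outer(a$x2, b$x2, pmin); iy2 <- outer(a$y2, b$y2, pmin)
  iw <- pmax(ix2 - ix1, 0); ih <- pmax(iy2 - iy1, 0)
  inter <- iw * ih
  aa <- box_area(a$x1, a$y1, a$x2, a$y2)
  ab <- box_area(b$x1, b$y1, b$x2, b$y2)
  inter / (outer(aa, ab, `+`) - inter)
}

#' Clip a box to an image extent
#'
#' @param b numeric vector `c(x1, y1, x2, y2)`.
#' @param width,height image extent in pixels (positive).
#' @return Clipped box; an error if clipping leaves no area (box entirely
#'   outside the image).
#' @export
clip_box <- function(b, width, height) {
  stopifnot(width > 0, height > 0)
  out <- c(max(b[1], 0), max(b[2], 0), min(b[3], width), min(b[4], height))
  if (out[1] >= out[3] || out[2] >= out[4]) {
    stop("box [", paste(signif(b, 6), collapse = ", "),
         "] lies entirely outside the ", width, "x", height, " image",
         call. = FALSE)
  }
  out
}

#' Convert between corner and x/y/width/height box representations
#'
#' COCO stores boxes as `[x, y, width, height]`; the package works in corner
#' coordinates `[x1, y1, x2, y2]`. The conversion is exact and round-trips
#' bit-identically.
#'
#' @param b numeric vector of four coordinates in the `from` dialect.
#' @param from,to one of `"corners"` or `"xywh"`.
#' @return Numeric vector of four coordinates in the `to` dialect.
#' @export
convert_box <- function(b, from = c("corners", "xywh"), to = c("xywh", "corners")) {
  from <- match.arg(from); to <- match.arg(to)
  corners <- if (from == "corners") b else c(b[1], b[2], b[1] + b[3], b[2] + b[4])
  check_boxes(data.frame(x1 = corners[1], y1 = corners[2],
                         x2 = corners[3], y2 = corners[4]))
  if (to == "corners") corners
  else c(corners[1], corners[2], corners[3] - corners[1], corners[4] - corners[2])
}
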