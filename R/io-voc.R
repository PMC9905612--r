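# Pascal VOC XML annotations. VOC stores 1-based inclusive integer pixel
# corners; the package works in 0-based continuous coordinates. The declared
# conversion subtracts 1 from xmin/ymin on read and adds it back (after
# rounding) on write, so round trips agree within the documented 1-pixel
# convention shift.

#' Read a directory of Pascal VOC XML annotations
#'
#' One XML file per image, each with `size` and `object/bndbox` entries.
#' Object names are mapped through the class alias table
#' ([lk_normalize_label()]); malformed boxes (`xmax <= xmin`) are rejected
#' with the file and object named.
#'
#' @param dir directory containing `.xml` files.
#' @return List with `gts` and `images` as in [read_coco_annotations()].
#'   Image ids are the XML file basenames.
#' @export
read_voc_xml <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(files) == 0) stop("no .xml files in ", dir, call. = FALSE)
  gt_rows <- list(); img_rows <- list()
  for (f in files) {
    doc <- xml2::read_xml(f)
    image_id <- sub("\\.xml$", "", basename(f))
    w <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
    h <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
    img_rows[[f]] <- data.frame(image_id = image_id, width = w, height = h,
                                stringsAsFactors = FALSE)
    objs <- xml2::xml_find_all(doc, ".//object")
    for (k in seq_along(objs)) {
      o <- objs[[k]]
      nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
      num <- function(tag) {
        as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
      }
      xmin <- num("xmin"); ymin <- num("ymin"); xmax <- num("xmax"); ymax <- num("ymax")
      if (any(!is.finite(c(xmin, ymin, xmax, ymax)))) {
        stop(basename(f), ", object ", k, ": missing or non-numeric bndbox",
             call. = FALSE)
      }
      if (xmax <= xmin || ymax <= ymin) {
        stop(basename(f), ", object ", k, ": degenerate bndbox (",
             xmin, ",", ymin, ",", xmax, ",", ymax, ")", call. = FALSE)
      }
      gt_rows[[paste0(f, "#", k)]] <- data.frame(
        image_id = image_id,
        x1 = xmin - 1, y1 = ymin - 1, x2 = xmax, y2 = ymax,
        label = lk_normalize_label(nm), stringsAsFactors = FALSE)
    }
  }
  gts <- if (length(gt_rows)) do.call(rbind, gt_rows) else {
    data.frame(image_id = character(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(gts) <- NULL
  gts$tags <- rep(list(character(0)), nrow(gts))
  images <- do.call(rbind, img_rows); rownames(images) <- NULL
  list(gts = validate_ground_truths(gts), images = images)
}

#' Write ground truths as Pascal VOC XML files
#'
#' Writes one XML per image into `dir`. Corners are rounded to integers and
#' shifted to VOC's 1-based inclusive convention (`xmin = round(x1) + 1`).
#'
#' @param gts ground-truth table.
#' @param images image table (image_id, width, height).
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_voc_xml <- function(gts, images, dir) {
  gts <- validate_ground_truths(gts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full_names <- c(NG = "neutrophil", BG = "basophil", EG = "eosinophil",
                  L = "lymphocyte", M = "monocyte")
  for (i in seq_len(nrow(images))) {
    id <- images$image_id[i]
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(id, ".jpg"))
    size <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(size, "width", as.character(images$width[i]))
    xml2::xml_add_child(size, "height", as.character(images$height[i]))
    xml2::xml_add_child(size, "depth", "3")
    g <- gts[gts$image_id == id, , drop = FALSE]
    for (k in seq_len(nrow(g))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", unname(full_names[g$label[k]]))
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(round(g$x1[k]) + 1))
      xml2::xml_add_child(bb, "ymin", as.character(round(g$y1[k]) + 1))
      xml2::xml_add_child(bb, "xmax", as.character(round(g$x2[k])))
      xml2::xml_add_child(bb, "ymax", as.character(round(g$y2[k])))
    }
    xml2::write_xml(doc, file.path(dir, paste0(id, ".xml")))
  }
  invisible(dir)
}
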