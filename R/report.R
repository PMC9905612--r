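# Report export. The CSV mirrors the standard results-table column order
# (mAP, mAP@IoU0.50, mAP@IoU0.75, mAR, then per-class AP in the order
# BG, EG, NG, M, L); per-class APs that are undefined because the class has
# no ground truths are emitted as an explicit NA token, never as 0.

report_columns <- function() {
  c("mAP", "mAP@IoU0.50", "mAP@IoU0.75", "mAR",
    "AP-BG", "AP-EG", "AP-NG", "AP-M", "AP-L")
}

report_row <- function(report) {
  pc <- report$per_class_ap
  stats::setNames(
    c(report$mAP, report$mAP50, report$mAP75, report$mAR,
      pc["BG"], pc["EG"], pc["NG"], pc["M"], pc["L"]),
    report_columns())
}

#' Write an evaluation report to JSON or CSV
#'
#' JSON carries the full report (headline metrics, per-class AP, confusion
#' matrix, tag accuracies); CSV carries the single headline row in the
#' standard column order. Both formats contain identical metric values.
#'
#' @param report an `eval_report` from [evaluate_detections()].
#' @param path output file.
#' @param format `"json"` or `"csv"` (default: inferred from the file
#'   extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    row <- report_row(report)
    df <- as.data.frame(as.list(row), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "NA")
  } else {
    obj <- list(
      mAP = report$mAP, `mAP@IoU0.50` = report$mAP50,
      `mAP@IoU0.75` = report$mAP75, mAR = report$mAR,
      per_class_ap = as.list(report$per_class_ap),
      confusion = list(labels = rownames(report$confusion),
                       counts = unname(apply(report$confusion, 1, as.list))),
      tag_accuracy = as.list(report$tag_accuracy))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Export PR curves for several classes and thresholds as one CSV
#'
#' @param dets,gts detection and ground-truth tables.
#' @param path output CSV.
#' @param classes classes to include (default all five).
#' @param thresholds IoU thresholds (default 0.50 and 0.75).
#' @return `path`, invisibly.
#' @export
write_pr_curves <- function(dets, gts, path, classes = lk_classes(),
                            thresholds = c(0.50, 0.75)) {
  curves <- do.call(rbind, lapply(thresholds, function(t) {
    do.call(rbind, lapply(classes, function(cl) pr_curve(dets, gts, t, cl)))
  }))
  utils::write.csv(curves, path, row.names = FALSE, na = "NA")
  invisible(path)
}
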