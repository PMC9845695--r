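# Confusion-matrix evaluation: overall accuracy (OA), average accuracy
# (AA, mean per-class recall) and mean intersection-over-union (mIoU),
# all reported as percentages. Ignored pixels never enter the matrix.

#' Accumulate a confusion matrix over one prediction/truth pair
#'
#' Adds per-pixel counts (rows = truth, columns = prediction) for pixels
#' whose truth label is not the ignore value. Accumulation is associative,
#' so patches can be tallied one at a time and summarised once.
#'
#' @param pred Integer prediction map (classes `0..C-1`).
#' @param truth Integer truth map of the same shape.
#' @param ignore Ignore value in `truth` (such pixels are skipped; predicted
#'   ignore values, e.g. unstitched gaps, are skipped too).
#' @param confusion Optional existing `C x C` matrix to add into.
#' @param n_classes Number of classes (required when `confusion` is `NULL`).
#' @return The updated `C x C` integer confusion matrix.
#' @export
accumulate_confusion <- function(pred, truth, ignore = 255L,
                                 confusion = NULL, n_classes = 4L) {
  if (!all(dim(pred) == dim(truth)) || length(pred) != length(truth)) {
    stop(sprintf("shape mismatch: pred %s vs truth %s",
                 paste(dim(pred) %||% length(pred), collapse = "x"),
                 paste(dim(truth) %||% length(truth), collapse = "x")))
  }
  C <- if (is.null(confusion)) as.integer(n_classes) else nrow(confusion)
  if (is.null(confusion)) confusion <- matrix(0L, C, C)
  t <- as.vector(truth); p <- as.vector(pred)
  keep <- t != ignore & p != ignore
  if (any(keep)) {
    t <- t[keep]; p <- p[keep]
    if (any(t < 0L | t >= C) || any(p < 0L | p >= C)) {
      stop("labels outside 0..C-1 encountered")
    }
    confusion <- confusion + matrix(tabulate(t + C * p + 1L, C * C), C, C)
  }
  confusion
}

#' Summarise a confusion matrix into OA / AA / mIoU
#'
#' OA is `100 * trace / total`; AA the mean per-class recall; mIoU the mean
#' per-class intersection-over-union. Classes absent from both truth and
#' prediction are excluded from the AA and mIoU means (AA additionally
#' requires truth support, avoiding 0/0 recalls).
#'
#' @param confusion `C x C` matrix with rows = truth, columns = prediction.
#' @return A `cropseg_metrics` list: `confusion`, `oa`, `aa`, `miou`,
#'   `per_class_recall`, `per_class_iou` (percentages; `NaN` for undefined
#'   classes).
#' @export
summarize_metrics <- function(confusion) {
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix")
  C <- nrow(confusion)
  diagv <- diag(confusion)
  truth_n <- rowSums(confusion)
  pred_n <- colSums(confusion)
  recall <- ifelse(truth_n > 0, diagv / truth_n, NaN)
  union <- truth_n + pred_n - diagv
  iou <- ifelse(union > 0, diagv / union, NaN)
  structure(list(
    confusion = confusion,
    oa = 100 * sum(diagv) / total,
    aa = 100 * mean(recall[truth_n > 0]),
    miou = 100 * mean(iou[union > 0]),
    per_class_recall = 100 * recall,
    per_class_iou = 100 * iou), class = "cropseg_metrics")
}

#' @export
print.cropseg_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("OA %.2f%%  AA %.2f%%  mIoU %.2f%%  (%s pixels)\n",
              x$oa, x$aa, x$miou, format(sum(x$confusion), big.mark = ",")))
  tab <- data.frame(recall = round(x$per_class_recall, digits),
                    iou = round(x$per_class_iou, digits))
  rownames(tab) <- paste0("class", seq_len(nrow(x$confusion)) - 1L)
  print(tab)
  invisible(x)
}

#' Write a metrics report to JSON and CSV
#'
#' @param report A `cropseg_metrics`.
#' @param path_json,path_csv Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(oa = report$oa, aa = report$aa, miou = report$miou,
           per_class_recall = report$per_class_recall,
           per_class_iou = report$per_class_iou,
           confusion = report$confusion),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    tab <- data.frame(class = seq_len(nrow(report$confusion)) - 1L,
                      recall_pct = report$per_class_recall,
                      iou_pct = report$per_class_iou)
    write.csv(tab, path_csv, row.names = FALSE)
  }
  invisible(report)
}
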