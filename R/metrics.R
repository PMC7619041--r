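#' Per-class segmentation metrics
#'
#' Categorical precision, recall, F1 and IoU between a predicted and a true
#' label map, on the percent scale. Per class,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, F1 is their
#' harmonic mean, and `IoU = TP / (TP + FP + FN)`; ratios with empty
#' denominators are 0. Macro averages run over the evaluated classes only:
#' classes absent from both prediction and truth are undefined and excluded.
#' Values are invariant to class ordering and to any simultaneous relabeling
#' of prediction and truth.
#'
#' @param pred,truth Integer label matrices of the same shape (0 =
#'   background, not scored as a class).
#' @param classes Classes to evaluate; default all nonzero labels present in
#'   either map.
#' @return An object of class `seg_metrics`: `per_class` data frame (class,
#'   precision, recall, f1, iou, support) and macro `precision`, `recall`,
#'   `f1`, `miou` in `[0, 100]`.
#' @examples
#' truth <- matrix(c(1, 1, 0, 0), 2, 2)
#' pred <- matrix(c(1, 0, 1, 0), 2, 2)
#' evaluate_segmentation(pred, truth)
#' @export
evaluate_segmentation <- function(pred, truth, classes = NULL) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must share the same grid", call. = FALSE)
  if (is.null(classes)) {
    classes <- sort(setdiff(union(unique(as.vector(pred)),
                                  unique(as.vector(truth))), 0L))
  }
  rows <- lapply(classes, function(k) {
    pm <- pred == k; tm <- truth == k
    tp <- sum(pm & tm); fp <- sum(pm & !tm); fn <- sum(!pm & tm)
    if (tp + fp + fn == 0L) return(NULL)  # absent from both: undefined
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    iou <- tp / (tp + fp + fn)
    data.frame(class = k, precision = 100 * prec, recall = 100 * rec,
               f1 = 100 * f1, iou = 100 * iou, support = tp + fn)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    stop("no class is present in either map; metrics undefined", call. = FALSE)
  structure(list(per_class = rows,
                 precision = mean(rows$precision), recall = mean(rows$recall),
                 f1 = mean(rows$f1), miou = mean(rows$iou)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> %d classes | precision %.2f  recall %.2f  F1 %.2f  mIoU %.2f\n",
              nrow(x$per_class), x$precision, x$recall, x$f1, x$miou))
  invisible(x)
}
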