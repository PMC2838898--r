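## Pixel-level evaluation inside the field of view: confusion counts,
## sensitivity / specificity / accuracy, and per-image aggregation.

#' Segmentation metrics inside the FOV
#'
#' Counts true/false positives/negatives over FOV pixels only and derives
#' sensitivity `tp/(tp+fn)` (properly classified vessel pixels),
#' specificity `tn/(tn+fp)` and accuracy `(tp+tn)/total`.  A metric with a
#' zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param pred Predicted vessel mask (logical matrix).
#' @param truth Ground-truth vessel mask of the same shape.
#' @param fov Optional FOV mask; `NULL` means all pixels count.
#' @return Object of class `seg_metrics`: list with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(pred, truth, fov = NULL) {
  assert_binary_map(pred)
  assert_binary_map(truth)
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!identical(dim(fov), dim(pred))) stop("FOV shape mismatch")
  p <- pred[fov]; t <- truth[fov]
  tp <- sum(p & t); fp <- sum(p & !t)
  tn <- sum(!p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 accuracy = ratio(tp + tn, tp + fp + tn + fn)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf(paste0("<seg_metrics: sens %.4f, spec %.4f, acc %.4f ",
                     "(tp %d, fp %d, tn %d, fn %d)>\n"),
              x$sensitivity, x$specificity, x$accuracy,
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Aggregate per-image metrics
#'
#' Unweighted per-image means (every image counts equally, not every
#' pixel), with the sample standard deviation (n - 1 denominator) of the
#' accuracy; for a single image the SD is `NA`.
#'
#' @param metrics List of [compute_metrics()] results (>= 1).
#' @return List with `mean_accuracy`, `sd_accuracy`, `mean_sensitivity`,
#'   `mean_specificity` and `n_images`.
#' @export
aggregate_metrics <- function(metrics) {
  if (!length(metrics)) stop("empty metrics list")
  acc <- vapply(metrics, function(m) m$accuracy, numeric(1L))
  sens <- vapply(metrics, function(m) m$sensitivity, numeric(1L))
  spec <- vapply(metrics, function(m) m$specificity, numeric(1L))
  list(mean_accuracy = mean(acc),
       sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else NA_real_,
       mean_sensitivity = mean(sens),
       mean_specificity = mean(spec),
       n_images = length(metrics))
}
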