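# Confusion-matrix evaluation of a segmentation against an expert mask,
# and Table-style batch summaries (mean +/- SD per indicator).

#' Confusion counts between a ground-truth and a predicted mask
#'
#' @param gt Binary ground-truth mask (expert segmentation).
#' @param pred Binary predicted mask of identical dimensions.
#' @return A list of class `"confusion_counts"` with integer fields
#'   `TP`, `TN`, `FP`, `FN` summing to the number of pixels.
#' @export
confusion_counts <- function(gt, pred) {
  gt <- as_binary_image(gt)
  pred <- as_binary_image(pred)
  assert_same_dim(gt, pred, "ground truth and prediction")
  tp <- sum(gt == 1L & pred == 1L)
  tn <- sum(gt == 0L & pred == 0L)
  fp <- sum(gt == 0L & pred == 1L)
  fn <- sum(gt == 1L & pred == 0L)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Segmentation performance indicators from confusion counts
#'
#' Computes the nine standard indicators: sensitivity (recall),
#' specificity, accuracy, precision, F-measure, Dice coefficient,
#' Matthews correlation coefficient, Jaccard index (IoU), and the
#' binary operating-point AUC `(sensitivity + specificity) / 2`.  Any
#' indicator whose denominator is zero is returned as `NA` (an explicit
#' undefined marker) rather than being silently forced to 0 or 1;
#' batch summaries exclude such entries.
#'
#' @param counts A `"confusion_counts"` object, or a list/vector with
#'   fields `TP`, `TN`, `FP`, `FN`.
#' @return A list of class `"metric_report"` with fields `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `f_measure`, `dice`,
#'   `mcc`, `jaccard`, `auc`.
#' @examples
#' metric_report(list(TP = 8, FP = 2, FN = 2, TN = 88))
#' @export
metric_report <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  if (anyNA(c(tp, tn, fp, fn)) || any(c(tp, tn, fp, fn) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  total <- tp + tn + fp + fn
  if (total == 0) {
    stop("confusion counts are all zero: nothing to evaluate", call. = FALSE)
  }
  se <- safe_ratio(tp, tp + fn)
  sp <- safe_ratio(tn, tn + fp)
  pr <- safe_ratio(tp, tp + fp)
  f  <- if (is.na(pr) || is.na(se) || pr + se == 0) NA_real_ else
    2 * pr * se / (pr + se)
  dice <- safe_ratio(2 * tp, 2 * tp + fp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    NA_real_
  } else if (fp == 0 && fn == 0) {
    1  # perfect agreement: exact, avoids sqrt round-off at the corner
  } else if (tp == 0 && tn == 0) {
    -1  # perfect disagreement
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  jac <- safe_ratio(tp, tp + fp + fn)
  auc <- if (is.na(se) || is.na(sp)) NA_real_ else (se + sp) / 2
  structure(list(
    sensitivity = se, specificity = sp,
    accuracy = (tp + tn) / total,
    precision = pr, f_measure = f, dice = dice, mcc = mcc, jaccard = jac,
    auc = auc
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat("Segmentation performance indicators\n")
  for (nm in names(v)) {
    cat(sprintf("  %-12s %s\n", nm,
                ifelse(is.na(v[[nm]]), "undefined",
                       formatC(v[[nm]], digits = digits, format = "f"))))
  }
  invisible(x)
}

#' Evaluate a predicted mask against ground truth
#'
#' Convenience composition of [confusion_counts()] and
#' [metric_report()].
#'
#' @inheritParams confusion_counts
#' @return A `"metric_report"`.
#' @export
evaluate_pair <- function(gt, pred) {
  metric_report(confusion_counts(gt, pred))
}

#' Threshold-sweep ROC AUC for a grayscale scorer
#'
#' Builds an ROC curve by sweeping the binarization threshold over
#' 0..255 inside the region of interest and integrates it with the
#' trapezoidal rule (operating points plus the (0,0) and (1,1)
#' endpoints).  Equivalent to the normalized Mann-Whitney statistic on
#' the pixel intensities of the two classes, with ties counted half.
#'
#' @param X Grayscale integer matrix.
#' @param gt Binary ground-truth mask.
#' @param roi Binary region-of-interest mask; only pixels inside it are
#'   ranked.
#' @param invert If `TRUE` (default), low intensities score as
#'   foreground (radiolucent lung); if `FALSE`, high intensities do.
#' @return AUC in \[0, 1\].
#' @export
auc_sweep <- function(X, gt, roi = NULL, invert = TRUE) {
  X <- as_gray_image(X)
  gt <- as_binary_image(gt)
  assert_same_dim(X, gt, "image and ground truth")
  if (is.null(roi)) {
    roi <- matrix(1L, nrow(X), ncol(X))
  }
  roi <- as_binary_image(roi)
  assert_same_dim(X, roi, "image and ROI")
  if (sum(roi) == 0L) stop("ROI is empty", call. = FALSE)
  inside <- roi == 1L
  y <- gt[inside]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined: ground truth inside the ROI has a single class",
         call. = FALSE)
  }
  x <- X[inside]
  tpr <- fpr <- numeric(256L)
  for (t in 0:255) {
    pred <- if (invert) x <= t else x > t
    tpr[t + 1L] <- sum(pred & y == 1L) / n1
    fpr[t + 1L] <- sum(pred & y == 0L) / n0
  }
  ord <- order(fpr, tpr)
  fx <- c(0, fpr[ord], 1)
  fy <- c(0, tpr[ord], 1)
  sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
}

#' Summarize indicator reports across a batch of images
#'
#' Per-indicator sample mean and sample standard deviation (n - 1
#' denominator; 0 when a single value), the layout used to report
#' segmentation performance over an image set as mean +/- SD.
#' Undefined (`NA`) entries are excluded indicator by indicator and
#' counted in `n_excluded`.
#'
#' @param reports A list of `"metric_report"` objects.
#' @return A data frame of class `"batch_metric_summary"` with one row
#'   per indicator and columns `metric`, `mean`, `sd`, `n_used`,
#'   `n_excluded`, plus attribute `n_images`.
#' @export
summarize_batch <- function(reports) {
  if (!length(reports)) {
    stop("summarize_batch needs at least one report", call. = FALSE)
  }
  if (inherits(reports, "metric_report")) reports <- list(reports)
  mat <- do.call(rbind, lapply(reports, function(r) unlist(r)))
  out <- data.frame(
    metric = colnames(mat),
    mean = NA_real_, sd = NA_real_,
    n_used = 0L, n_excluded = 0L,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(mat))) {
    v <- mat[, k]
    ok <- !is.na(v)
    out$n_used[k] <- sum(ok)
    out$n_excluded[k] <- sum(!ok)
    if (any(ok)) {
      out$mean[k] <- mean(v[ok])
      out$sd[k] <- if (sum(ok) > 1L) sd(v[ok]) else 0
    }
  }
  attr(out, "n_images") <- length(reports)
  class(out) <- c("batch_metric_summary", "data.frame")
  out
}
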