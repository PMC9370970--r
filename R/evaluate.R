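#' Confusion matrix for regular/irregular labels
#'
#' Counts TP/FP/FN/TN with *irregular* as the positive class (the class a
#' sorting line wants to catch).
#'
#' @param pred,truth equal-length character vectors of `"regular"` /
#'   `"irregular"` labels.
#' @param positive positive-class label (default `"irregular"`).
#' @return a `confusion_matrix` object (fields `tp`, `fp`, `fn`, `tn`).
#' @seealso [confusion_counts()] to build one directly from counts.
#' @export
confusion_matrix <- function(pred, truth, positive = "irregular") {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    stop_tuber("`pred` and `truth` must be nonempty and of equal length",
               "tubershape_arg_error")
  }
  pred_pos <- pred == positive
  truth_pos <- truth == positive
  confusion_counts(tp = sum(pred_pos & truth_pos),
                   fp = sum(pred_pos & !truth_pos),
                   fn = sum(!pred_pos & truth_pos),
                   tn = sum(!pred_pos & !truth_pos),
                   positive = positive)
}

#' Confusion matrix from raw counts
#'
#' @param tp,fp,fn,tn nonnegative counts, at least one positive.
#' @param positive positive-class label (default `"irregular"`).
#' @return a `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive = "irregular") {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || sum(counts) < 1) {
    stop_tuber("counts must be nonnegative with at least one sample",
               "tubershape_arg_error")
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (positive = %s):\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and the
#' F1 score (harmonic mean of precision and recall).  A metric whose
#' denominator is zero is reported as `NA` (an explicit undefined marker),
#' never as an error.  With imbalanced classes — irregular tubers are the
#' minority — precision/recall/F1 are the primary metrics and accuracy is
#' secondary.
#'
#' @param cm a [confusion_matrix()] object.
#' @return a `classification_metrics` object: named list with `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' classification_metrics(confusion_counts(tp = 49, fp = 3, fn = 1, tn = 95))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  recall <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(list(accuracy = ratio(cm$tp + cm$tn, total),
                 precision = precision, recall = recall, f1 = f1),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
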