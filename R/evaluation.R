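## Confusion matrices and classification metrics.  For single-label
## multiclass tasks, micro-averaged precision and recall both equal
## accuracy (pooled TP equals the diagonal total); the headline F1 is
## macro-averaged.  Both conventions are labeled explicitly in reports.

#' Confusion matrix from actual and predicted class indices
#'
#' @param actual,predicted equal-length vectors of 0-based class indices.
#' @param k number of classes.
#' @return `confusion_matrix`: a k x k integer matrix, rows = actual,
#'   columns = predicted.
#' @export
confusion_matrix <- function(actual, predicted, k) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) && (max(actual, predicted) >= k || min(actual, predicted) < 0)) {
    stop("class indices must lie in 0..k-1", call. = FALSE)
  }
  cm <- matrix(0L, k, k)
  for (i in seq_along(actual)) {
    cm[actual[i] + 1L, predicted[i] + 1L] <- cm[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' The proportion of correct predictions: the diagonal total over the
#' grand total (equivalently (TP + TN) / (TP + TN + FP + FN) in the binary
#' case).
#'
#' @param cm a [confusion_matrix()].
#' @return proportion in \[0, 1\].
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix: accuracy undefined", call. = FALSE)
  sum(diag(cm)) / tot
}

#' Per-class precision and recall
#'
#' Precision TP/(TP+FP) (positive predictive value) and recall TP/(TP+FN)
#' (sensitivity) for one class; 0/0 is defined as 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @param class 0-based class index.
#' @return named vector `c(precision, recall)`.
#' @export
precision_recall <- function(cm, class) {
  j <- class + 1L
  tp <- cm[j, j]
  pred <- sum(cm[, j])
  act <- sum(cm[j, ])
  if (pred == 0 || act == 0) {
    warning("class ", class, ": 0/0 precision or recall defined as 0",
            call. = FALSE)
  }
  c(precision = if (pred == 0) 0 else tp / pred,
    recall = if (act == 0) 0 else tp / act)
}

per_class_table <- function(cm) {
  k <- nrow(cm)
  out <- t(vapply(seq_len(k) - 1L, function(c) {
    pr <- suppressWarnings(precision_recall(cm, c))
    f1 <- if (pr[1] + pr[2] == 0) 0 else 2 * pr[1] * pr[2] / (pr[1] + pr[2])
    c(pr, f1 = f1)
  }, numeric(3)))
  data.frame(class = seq_len(k) - 1L, precision = out[, 1],
             recall = out[, 2], f1 = out[, 3])
}

#' Micro- or macro-averaged precision, recall and F1
#'
#' Micro averaging pools TP/FP/FN over classes before computing the
#' metric (for single-label tasks micro precision = micro recall =
#' accuracy); macro averaging is the unweighted mean of per-class values.
#'
#' @param cm a [confusion_matrix()].
#' @param averaging `"micro"` or `"macro"`.
#' @return named vector `c(precision, recall, f1)`.
#' @export
aggregate_metrics <- function(cm, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  if (averaging == "micro") {
    tp <- sum(diag(cm))
    fp <- sum(colSums(cm) - diag(cm))
    fn <- sum(rowSums(cm) - diag(cm))
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  } else {
    tab <- per_class_table(cm)
    p <- mean(tab$precision)
    r <- mean(tab$recall)
    return(c(precision = p, recall = r, f1 = mean(tab$f1)))
  }
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Evaluate a fitted model on a dataset
#'
#' @param model a fitted `ecg_model` or `ecg_fit`.
#' @param dataset an `ecg_dataset`.
#' @return `eval_report`: scenario name, partition, confusion matrix,
#'   accuracy, micro precision/recall, macro F1 and the per-class table.
#' @export
evaluate <- function(model, dataset) {
  pred <- predict_class(model, dataset)
  cm <- confusion_matrix(dataset$y, pred, dataset$scenario$k)
  micro <- aggregate_metrics(cm, "micro")
  macro <- aggregate_metrics(cm, "macro")
  per_class <- per_class_table(cm)
  per_class$class <- dataset$scenario$class_names
  structure(list(
    scenario = dataset$scenario$name, partition = dataset$partition,
    class_names = dataset$scenario$class_names, confusion = cm,
    accuracy = accuracy(cm),
    precision_micro = micro[["precision"]], recall_micro = micro[["recall"]],
    f1_macro = macro[["f1"]], per_class = per_class
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation: %s / %s (%d records)\n", x$scenario, x$partition,
              sum(x$confusion)))
  cat(sprintf("  accuracy %.4f | micro P/R %.4f/%.4f | macro F1 %.4f\n",
              x$accuracy, x$precision_micro, x$recall_micro, x$f1_macro))
  cm <- unclass(x$confusion)
  dimnames(cm) <- list(actual = x$class_names, predicted = x$class_names)
  print(cm)
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an [evaluate()] result.
#' @param path optional output file; when omitted the JSON string is
#'   returned.
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(scenario = report$scenario, partition = report$partition,
            class_names = report$class_names,
            confusion = unclass(report$confusion),
            accuracy = report$accuracy,
            precision_micro = report$precision_micro,
            recall_micro = report$recall_micro,
            f1_macro = report$f1_macro, per_class = report$per_class)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
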