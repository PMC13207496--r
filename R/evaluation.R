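#' Confusion matrix from integer label vectors
#'
#' Entry `(i, j)` counts samples with true class `i` predicted as class
#' `j`; classes are `1..n_classes`.
#'
#' @param true_labels,predicted_labels equal-length integer vectors.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` integer count matrix.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, n_classes) {
  if (length(true_labels) == 0) stop("confusion_matrix: empty input")
  if (length(true_labels) != length(predicted_labels)) {
    stop("confusion_matrix: length mismatch")
  }
  labs <- c(true_labels, predicted_labels)
  if (any(labs < 1 | labs > n_classes | labs != floor(labs))) {
    stop("confusion_matrix: label out of range")
  }
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels)) {
    m[true_labels[i], predicted_labels[i]] <- m[true_labels[i], predicted_labels[i]] + 1L
  }
  m
}

#' Macro-averaged metrics from a confusion matrix
#'
#' Per-class precision, recall and F1 with the conservative 0/0 := 0
#' convention (a class with no predictions, or no members, scores 0 and
#' still counts in the macro mean); macro values are unweighted class
#' means. Recall equals sensitivity for the positive class of a binary
#' task. Binary tasks report the same macro quantities as multiclass ones.
#'
#' @param confusion square count matrix from [confusion_matrix()].
#' @return metrics report: `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `per_class` data frame, `confusion`, `n_eval`.
#' @export
macro_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion),
            all(confusion >= 0))
  n_eval <- sum(confusion)
  stopifnot(n_eval > 0)
  tp <- diag(confusion)
  pred_tot <- colSums(confusion)
  true_tot <- rowSums(confusion)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, pred_tot)
  recall <- safe_div(tp, true_tot)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  structure(list(
    accuracy = sum(tp) / n_eval,
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    per_class = data.frame(class = seq_len(nrow(confusion)),
                           precision = precision, recall = recall, f1 = f1),
    confusion = confusion,
    n_eval = n_eval
  ), class = "fldpsim_metrics")
}

#' Evaluate a model on a labeled feature matrix
#'
#' Predicts with [predict_proba()], takes the argmax (first index on ties)
#' and returns the macro metrics report. Predicted probabilities are kept
#' on the report (`proba`) so threshold-based metrics can be added
#' downstream.
#'
#' @param w flat parameter vector.
#' @param spec a [model_spec()].
#' @param X,y evaluation features and integer labels.
#' @return metrics report (see [macro_metrics()]).
#' @export
evaluate_model <- function(w, spec, X, y) {
  P <- predict_proba(w, spec, X)
  pred <- max.col(P, ties.method = "first")
  rep <- macro_metrics(confusion_matrix(y, pred, spec$n_classes))
  rep$proba <- P
  rep
}

#' Write a metrics report as JSON
#' @param report a metrics report.
#' @param path output path.
#' @export
write_metrics <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              macro_precision = report$macro_precision,
              macro_recall = report$macro_recall,
              macro_f1 = report$macro_f1,
              confusion = report$confusion,
              n_eval = report$n_eval)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
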