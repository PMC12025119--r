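# Confusion-matrix metrics with exact binomial confidence intervals.

#' Build a 2x2 confusion matrix
#'
#' Cell (i, j) counts samples predicted as class i and observed as class j.
#' Class order follows `class_order` (negative class first, positive class
#' second).
#'
#' @param pred Predicted label vector.
#' @param obs Observed label vector, same length.
#' @param class_order Character pair giving (negative, positive) class.
#' @return 2x2 integer matrix of class `confusion_matrix_2x2`, dimnames
#'   `predicted` x `observed`.
#' @export
confusion_matrix <- function(pred, obs, class_order = sort(unique(c(pred, obs)))) {
  if (length(pred) != length(obs)) stop_rohcnn("length mismatch")
  if (length(pred) == 0) stop_rohcnn("empty label vectors")
  if (length(class_order) != 2) stop_rohcnn("exactly two classes required")
  if (!all(c(pred, obs) %in% class_order)) stop_rohcnn("unknown label")
  cm <- table(factor(pred, levels = class_order),
              factor(obs, levels = class_order))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(predicted = class_order,
                               observed = class_order))
  structure(cm, class = c("confusion_matrix_2x2", class(cm)))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from beta-distribution quantiles:
#' lower = qbeta(alpha/2, s, n - s + 1) (0 when s = 0),
#' upper = qbeta(1 - alpha/2, s + 1, n - s) (1 when s = n).
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param alpha Two-sided error rate (default 0.05).
#' @return Numeric pair (low, high).
#' @export
exact_binomial_ci <- function(successes, n, alpha = 0.05) {
  if (n < 1 || successes < 0 || successes > n) {
    stop_rohcnn("invalid counts: ", successes, "/", n)
  }
  low <- if (successes == 0) 0 else {
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  }
  high <- if (successes == n) 1 else {
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  }
  c(low = low, high = high)
}

#' Confusion-matrix classification metrics
#'
#' With the positive class P and negative class N:
#' TP = (pred P, obs P), TN = (pred N, obs N), FP = (pred P, obs N),
#' FN = (pred N, obs P); accuracy = (TP+TN)/total with a Clopper-Pearson
#' 95% CI, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN). A zero denominator yields `NA`
#' (undefined), never 0. Values are returned unrounded; use
#' [format.metrics_report()] for 4-decimal display.
#'
#' @param cm A [confusion_matrix()].
#' @param positive_class Name of the positive (case) class; default the
#'   second class of the matrix order.
#' @param alpha CI error rate (default 0.05).
#' @return List of class `metrics_report`: accuracy, ci_low, ci_high,
#'   sensitivity, specificity, ppv, npv, positive_class, n.
#' @export
classification_metrics <- function(cm, positive_class = colnames(cm)[2],
                                   alpha = 0.05) {
  classes <- colnames(cm)
  if (!positive_class %in% classes) stop_rohcnn("unknown positive class")
  pos <- positive_class
  neg <- setdiff(classes, pos)
  tp <- cm[pos, pos]; tn <- cm[neg, neg]
  fp <- cm[pos, neg]; fn <- cm[neg, pos]
  total <- tp + tn + fp + fn
  if (total == 0) stop_rohcnn("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  ci <- exact_binomial_ci(tp + tn, total, alpha)
  structure(list(accuracy = (tp + tn) / total,
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 sensitivity = safe_div(tp, tp + fn),
                 specificity = safe_div(tn, tn + fp),
                 ppv = safe_div(tp, tp + fp),
                 npv = safe_div(tn, tn + fn),
                 positive_class = pos, n = as.integer(total)),
            class = "metrics_report")
}

#' @export
format.metrics_report <- function(x, ...) {
  sprintf(paste0("Accuracy %.4f (95%% CI %.4f-%.4f)  Sensitivity %.4f  ",
                 "Specificity %.4f  PPV %.4f  NPV %.4f  [positive: %s]"),
          x$accuracy, x$ci_low, x$ci_high, x$sensitivity, x$specificity,
          x$ppv, x$npv, x$positive_class)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Write a metrics report (and optional confusion matrix) to JSON and text
#'
#' @param report A `metrics_report`.
#' @param path JSON output path; a sibling `.txt` confusion-matrix file is
#'   written when `cm` is supplied.
#' @param cm Optional [confusion_matrix()].
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(report, path, cm = NULL) {
  jsonlite::write_json(report[c("accuracy", "ci_low", "ci_high",
                                "sensitivity", "specificity", "ppv", "npv",
                                "positive_class", "n")],
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cm)) {
    txt <- utils::capture.output(print(unclass(cm)))
    writeLines(c(txt, "", format(report)),
               sub("\\.json$", ".txt", path))
  }
  invisible(path)
}
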