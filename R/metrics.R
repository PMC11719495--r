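#' Confusion matrix for binary epilepsy/normal predictions
#'
#' Epilepsy is the positive class: TP counts segments correctly predicted
#' epileptic, TN segments correctly predicted normal.
#'
#' @param y_true,y_pred equal-length vectors; either 0/1 (1 = epilepsy) or
#'   the labels `"epilepsy"` / `"normal"`
#' @return object of class `confusion_matrix` with fields tp, fp, fn, tn
#' @export
confusion <- function(y_true, y_pred) {
  stop_if(length(y_true) != length(y_pred), "y_true and y_pred lengths differ")
  to01 <- function(y) {
    if (is.character(y) || is.factor(y)) {
      y <- as.character(y)
      stop_if(!all(y %in% c("epilepsy", "normal")), "labels must be 'epilepsy' or 'normal'")
      as.integer(y == "epilepsy")
    } else {
      stop_if(!all(y %in% c(0, 1)), "numeric labels must be 0/1")
      as.integer(y)
    }
  }
  yt <- to01(y_true)
  yp <- to01(y_pred)
  confusion_matrix(tp = sum(yt == 1 & yp == 1), fp = sum(yt == 0 & yp == 1),
                   fn = sum(yt == 1 & yp == 0), tn = sum(yt == 0 & yp == 0))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative counts
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stop_if(any(counts < 0) || any(counts != round(counts)),
          "confusion counts must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Five-score evaluation report from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` and the F1 score
#' `2 * precision * sensitivity / (precision + sensitivity)`. A score whose
#' denominator is zero is reported as 0 with a warning, so parameter sweeps
#' never abort on a degenerate split.
#'
#' @param cm a [confusion_matrix()]
#' @return object of class `metrics_report`: accuracy, sensitivity,
#'   specificity, precision, f1, all fractions in `[0, 1]`
#' @export
score <- function(cm) {
  stop_if(!inherits(cm, "confusion_matrix"), "cm must be a confusion_matrix")
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  stop_if(total == 0, "empty confusion matrix")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0")
      0
    } else num / den
  }
  sens <- safe_div(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- safe_div(cm$tn, cm$tn + cm$fp, "specificity")
  prec <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(accuracy = (cm$tp + cm$tn) / total, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x)
  cat("<metrics_report> (%)\n")
  for (n in names(v)) cat(sprintf("  %-12s %6.2f\n", n, 100 * v[[n]]))
  invisible(x)
}

#' Format a metrics report as a Table-2-style row
#'
#' Percentages at two decimal places alongside the experiment parameters.
#'
#' @param report a [score()] result
#' @param input_size `(height, width)` of the network input
#' @param optimizer,learning_rate training parameters
#' @return one-row data.frame
#' @export
report_row <- function(report, input_size, optimizer, learning_rate) {
  data.frame(input_size = paste(input_size, collapse = " x "),
             optimizer = optimizer, learning_rate = learning_rate,
             accuracy = round(100 * report$accuracy, 2),
             sensitivity = round(100 * report$sensitivity, 2),
             specificity = round(100 * report$specificity, 2),
             precision = round(100 * report$precision, 2),
             f1 = round(100 * report$f1, 2))
}
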