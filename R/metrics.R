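#' Confusion matrix for binary classification
#'
#' Standard counts with class 1 = disease presence: `tp` (true 1 predicted
#' 1), `tn`, `fp` (true 0 predicted 1), `fn`.
#'
#' @param truth Binary vector of true labels.
#' @param estimate Binary vector of predicted labels, same length.
#' @return An object of class `confusion`: list with integer `tp`, `tn`,
#'   `fp`, `fn`. [confusion_counts()] builds one directly from the four
#'   counts.
#' @examples
#' confusion_matrix(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' @export
confusion_matrix <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have the same length", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1)) || !all(estimate %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  confusion_counts(tp = sum(truth == 1 & estimate == 1),
                   tn = sum(truth == 0 & estimate == 0),
                   fp = sum(truth == 0 & estimate == 1),
                   fn = sum(truth == 1 & estimate == 0))
}

#' @rdname confusion_matrix
#' @param tp,tn,fp,fn Nonnegative counts (at least one positive).
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("1", "0"), predicted = c("1", "0")))
  print(m)
  invisible(x)
}

#' The ten-metric classification report
#'
#' Computes the standard confusion-matrix derived metrics: accuracy,
#' sensitivity (identically equal to recall; the report carries a single
#' column for the quantity), specificity, precision, F1 score
#' `2 * precision * sensitivity / (precision + sensitivity)`, the Matthews
#' correlation coefficient, negative predictive value, false positive rate
#' `fp / (fp + tn) = 1 - specificity`, and false negative rate
#' `fn / (fn + tp) = 1 - sensitivity`.
#'
#' Metrics with a zero denominator are returned as `NA` and listed in the
#' `"undefined"` attribute; a zero MCC denominator yields `mcc = 0` with the
#' flag, the common convention.
#'
#' @param x A `confusion` object, or a vector of true labels (with
#'   `estimate` supplied).
#' @param estimate Predicted labels when `x` is a label vector.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `mcc`, `npv`, `fpr`, `fnr` and an
#'   `"undefined"` attribute naming flagged entries.
#' @examples
#' classification_metrics(confusion_counts(tp = 50, tn = 40, fp = 5, fn = 5))
#' @export
classification_metrics <- function(x, estimate = NULL) {
  cm <- if (inherits(x, "confusion")) x else confusion_matrix(x, estimate)
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      NA_real_
    } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(sens) || is.na(prec) || prec + sens == 0) {
    undefined <- c(undefined, "f1")
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    undefined <- c(undefined, "mcc")
    0
  } else (tp * tn - fp * fn) / mcc_den
  out <- tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    f1 = f1,
    mcc = mcc,
    npv = safe(tn, tn + fn, "npv"),
    fpr = safe(fp, fp + tn, "fpr"),
    fnr = safe(fn, fn + tp, "fnr")
  )
  attr(out, "undefined") <- unique(undefined)
  out
}

#' @describeIn confusion_matrix Counts as a one-row tibble.
#' @param x A `confusion`.
#' @param ... Unused.
#' @method tidy confusion
#' @export
tidy.confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn)
}

#' @describeIn confusion_matrix Full metric report for the counts.
#' @method glance confusion
#' @export
glance.confusion <- function(x, ...) classification_metrics(x)
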