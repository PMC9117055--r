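#' Pixelwise confusion counts
#'
#' Compares a predicted binary tumor mask against ground truth, with tumor
#' as the positive class.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return Object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`; the four counts sum to the number of pixels.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have equal shapes", call. = FALSE)
  pred <- as.logical(pred); truth <- as.logical(truth)
  structure(list(tp = sum(pred & truth), tn = sum(!pred & !truth),
                 fp = sum(pred & !truth), fn = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Confusion-matrix performance metrics
#'
#' Computes, from the four confusion counts:
#' accuracy = (TP+TN)/(TP+TN+FP+FN) (reported in percent),
#' sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), and
#' F-measure = 2 * precision * recall / (precision + recall).
#' A ratio whose denominator is zero is reported as 0 and its name recorded
#' in the `undefined` field, so degenerate segmentations produce clean
#' summaries while remaining detectable.
#'
#' @param counts a [confusion_counts()] result (or list with tp/tn/fp/fn).
#' @return Object of class `seg_metrics`: list with `precision`,
#'   `sensitivity`, `specificity`, `f_measure` (ratios in \[0, 1\]),
#'   `accuracy` (percent) and `undefined` (character vector).
#' @export
#' @examples
#' compute_metrics(list(tp = 8, fp = 2, fn = 1, tn = 5))
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no pixels to compare", call. = FALSE)
  undefined <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  f_measure <- ratio(2 * precision * sensitivity, precision + sensitivity,
                     "f_measure")
  structure(list(precision = precision, sensitivity = sensitivity,
                 specificity = specificity, f_measure = f_measure,
                 accuracy = 100 * (tp + tn) / total, undefined = undefined),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("precision %.4f  sensitivity %.4f  specificity %.4f  F %.4f  accuracy %.2f%%\n",
              x$precision, x$sensitivity, x$specificity, x$f_measure,
              x$accuracy))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)` for two binary masks. Not part of the
#' confusion-matrix metric set; used to score phantom segmentations against
#' their exact ground truth. Two empty masks have Dice 1 by convention.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have equal shapes", call. = FALSE)
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Summarise a metrics table
#'
#' Arithmetic mean, minimum and maximum of each metric column over a set of
#' per-sample records. With `display_digits`, the *mean* row is truncated
#' (floored, not rounded) to the given number of decimals per metric —
#' matching how benchmark summary figures are conventionally printed.
#'
#' @param records data.frame with one row per sample; all numeric columns
#'   except `sample` and `variant` are summarised.
#' @param display_digits optional named integer vector, e.g.
#'   `c(precision = 2, accuracy = 2)`: truncation digits for the mean row.
#' @return data.frame with a `stat` column (`mean`, `min`, `max`) and one
#'   column per metric.
#' @export
summarize_metrics <- function(records, display_digits = NULL) {
  if (nrow(records) == 0) stop("empty records", call. = FALSE)
  num <- records[setdiff(names(records), c("sample", "variant"))]
  num <- num[vapply(num, is.numeric, TRUE)]
  out <- data.frame(stat = c("mean", "min", "max"))
  for (nm in names(num)) {
    m <- mean(num[[nm]])
    if (!is.null(display_digits) && nm %in% names(display_digits))
      m <- truncate_value(m, display_digits[[nm]])
    out[[nm]] <- c(m, min(num[[nm]]), max(num[[nm]]))
  }
  out
}

#' Truncate (floor) a value to a number of decimals
#'
#' `truncate_value(0.8957, 2)` is `0.89`, not `0.90`. Used for display
#' summaries that truncate rather than round.
#'
#' @param x numeric.
#' @param digits decimal places kept.
#' @return Truncated value(s).
#' @export
truncate_value <- function(x, digits) floor(x * 10^digits) / 10^digits

#' Packaged reference benchmark tables
#'
#' Per-sample performance values (precision, sensitivity, F-measure,
#' accuracy in percent, specificity, segmentation time in seconds) reported
#' for the three algorithm configurations on a ten-image MRI benchmark.
#' Shipped as plain CSV under `extdata/`; used to validate the summary
#' statistics machinery against published figures.
#'
#' @param variant one of `"multiobjective_modified"`,
#'   `"single_objective_modified"`, `"single_objective_basic"`.
#' @return data.frame with 10 rows and columns `sample`, `precision`,
#'   `sensitivity`, `f_measure`, `accuracy`, `specificity`, `time_s`.
#' @export
reference_metrics <- function(variant = c("multiobjective_modified",
                                          "single_objective_modified",
                                          "single_objective_basic")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("reference_", variant, ".csv"),
                      package = "abcseg", mustWork = TRUE)
  utils::read.csv(path)
}
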