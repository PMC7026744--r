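# Detection performance: the four confusion counts and the five derived
# metrics (sensitivity, specificity, PPV, NPV, accuracy), with report writers
# in the conventional column order.

#' Confusion counts for binary detection
#'
#' Counts true/false positives and negatives for 0/1 label sequences, with 1
#' the cancer (positive) class.
#'
#' @param predicted Predicted labels in `{0, 1}`.
#' @param truth True labels in `{0, 1}`, same length.
#' @return An object of class `"confusion_counts"` with integer fields `tp`
#'   (correctly detected cancer cases), `fn` (missed cancer cases), `tn`
#'   (correctly detected healthy cases), `fp` (healthy cases flagged as
#'   cancer).  The four counts partition the samples.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_invalid("predicted (%d) and truth (%d) must have equal length",
                 length(predicted), length(truth))
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop_invalid("labels must be binary (0 = healthy, 1 = cancer)")
  }
  structure(list(tp = sum(predicted == 1 & truth == 1),
                 fn = sum(predicted == 0 & truth == 1),
                 tn = sum(predicted == 0 & truth == 0),
                 fp = sum(predicted == 1 & truth == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fn=%d tn=%d fp=%d (n=%d)\n",
              x$tp, x$fn, x$tn, x$fp, x$tp + x$fn + x$tn + x$fp))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Detection performance metrics
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive
#' predictive value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)`, and
#' accuracy `(tp+tn)/n` from confusion counts.  A zero denominator yields
#' `NA` for that metric rather than an error.
#'
#' @param counts A [confusion_counts()] object (or a list with fields `tp`,
#'   `fn`, `tn`, `fp`).
#' @return An object of class `"metric_report"`: a list with the five metrics
#'   (each in `[0, 1]` or `NA`) and the counts.
#' @examples
#' performance_metrics(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 0)))
#' @export
performance_metrics <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop_invalid("counts must be non-negative")
  n <- tp + fn + tn + fp
  if (n == 0) stop_invalid("at least one sample is required")
  structure(list(sensitivity = safe_ratio(tp, tp + fn),
                 specificity = safe_ratio(tn, tn + fp),
                 ppv = safe_ratio(tp, tp + fp),
                 npv = safe_ratio(tn, tn + fn),
                 accuracy = (tp + tn) / n,
                 counts = counts),
            class = "metric_report")
}

metric_row <- function(x, label = "CNN/WOA") {
  data.frame(Method = label,
             Sensitivity = round(x$sensitivity, 2),
             Specificity = round(x$specificity, 2),
             PPV = round(x$ppv, 2),
             NPV = round(x$npv, 2),
             Accuracy = round(x$accuracy, 2),
             stringsAsFactors = FALSE)
}

#' @export
print.metric_report <- function(x, ...) {
  row <- metric_row(x)
  print(format(row[-1], nsmall = 2), row.names = FALSE)
  invisible(x)
}

#' Write a performance report
#'
#' One row per run in the conventional column order (Sensitivity,
#' Specificity, PPV, NPV, Accuracy), rounded to two decimals; undefined
#' metrics are rendered as `NA`.
#'
#' @param reports A `"metric_report"` or a named list of them (names become
#'   the Method column).
#' @param path Output path.
#' @param format `"csv"` or `"txt"` (plain-text table).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(reports, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  if (inherits(reports, "metric_report")) reports <- list(`CNN/WOA` = reports)
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    metric_row(reports[[nm]], nm)
  }))
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, na = "NA")
  } else {
    writeLines(capture_table(tab), path)
  }
  invisible(path)
}

capture_table <- function(tab) {
  utils::capture.output(print(format(tab, nsmall = 2), row.names = FALSE))
}
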