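#' Confusion matrix from binary labels and calls
#'
#' @param labels Binary truth (0/1).
#' @param calls Binary predictions (0/1), same length.
#' @return A `confusion_matrix`: list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls)) {
    stop("labels and calls differ in length")
  }
  stopifnot(all(labels %in% c(0, 1)), all(calls %in% c(0, 1)))
  structure(
    list(
      tp = sum(labels == 1 & calls == 1),
      fp = sum(labels == 0 & calls == 1),
      tn = sum(labels == 0 & calls == 0),
      fn = sum(labels == 1 & calls == 0)
    ),
    class = "confusion_matrix"
  )
}

#' Confusion matrix from counts
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_matrix")
}

frac_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Sensitivity (recall), percent
#' @param cm A `confusion_matrix`.
#' @return `100 * tp / (tp + fn)`; `NA` when undefined.
#' @export
sensitivity <- function(cm) frac_pct(cm$tp, cm$tp + cm$fn)

#' Specificity, percent
#' @param cm A `confusion_matrix`.
#' @return `100 * tn / (tn + fp)`; `NA` when undefined.
#' @export
specificity <- function(cm) frac_pct(cm$tn, cm$tn + cm$fp)

#' Accuracy, percent
#' @param cm A `confusion_matrix`.
#' @return `100 * (tp + tn) / n`; `NA` when undefined.
#' @export
accuracy <- function(cm) frac_pct(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn)

#' F-measure
#'
#' `2 * P * R / (P + R)` with precision `P = tp / (tp + fp)` and recall
#' `R = tp / (tp + fn)`; defined as 0 when `P + R` is 0 (no true positives).
#'
#' @param cm A `confusion_matrix`.
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(cm) {
  if (cm$tp == 0) return(0)
  p <- cm$tp / (cm$tp + cm$fp)
  r <- cm$tp / (cm$tp + cm$fn)
  2 * p * r / (p + r)
}

#' Metric report for a confusion matrix
#'
#' Raw values are unrounded; the `display` column rounds percentages to one
#' decimal for presentation.
#'
#' @param cm A `confusion_matrix`.
#' @return Tibble with `metric`, `value`, `display`.
#' @export
metric_report <- function(cm) {
  vals <- c(
    sensitivity = sensitivity(cm),
    specificity = specificity(cm),
    accuracy = accuracy(cm),
    f_measure = f_measure(cm),
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn
  )
  tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    display = ifelse(
      names(vals) %in% c("sensitivity", "specificity", "accuracy"),
      sprintf("%.1f", vals),
      as.character(signif(vals, 6))
    )
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(
    "<confusion_matrix> tp ", x$tp, ", fp ", x$fp, ", tn ", x$tn,
    ", fn ", x$fn, "\n",
    sep = ""
  )
  invisible(x)
}
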