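#' Binary confusion matrix and performance measures
#'
#' `binary_confusion()` builds a 2x2 confusion record from aggregate
#' counts; `confusion_from_labels()` tallies one from truth/prediction
#' vectors. `compute_measures()` derives the three standard measures:
#' accuracy `(tp+tn)/(tp+fn+fp+tn)`, sensitivity `tp/(tp+fn)` and
#' specificity `tn/(tn+fp)`. The positive class plays the role of the
#' null-hypothesis group in pairwise burn classification.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param positive Label of the positive (null-hypothesis) class.
#' @return `binary_confusion()`: an object of class `confusion_binary`.
#'   `compute_measures()`: a one-row tibble with `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
#' @examples
#' compute_measures(binary_confusion(tp = 36, fn = 3, fp = 2, tn = 35))
binary_confusion <- function(tp, fn, fp, tn, positive = "positive") {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), positive = positive, class = "confusion_binary")
}

#' @rdname binary_confusion
#' @param truth,predicted Vectors of true and predicted labels.
#' @export
confusion_from_labels <- function(truth, predicted, positive) {
  stopifnot(length(truth) == length(predicted))
  binary_confusion(
    tp = sum(truth == positive & predicted == positive),
    fn = sum(truth == positive & predicted != positive),
    fp = sum(truth != positive & predicted == positive),
    tn = sum(truth != positive & predicted != positive),
    positive = positive
  )
}

#' @rdname binary_confusion
#' @param cm A `confusion_binary` object.
#' @export
compute_measures <- function(cm) {
  stopifnot(inherits(cm, "confusion_binary"))
  pos_total <- cm$tp + cm$fn
  neg_total <- cm$tn + cm$fp
  if (pos_total == 0L || neg_total == 0L) {
    stop("both classes must have evaluated samples", call. = FALSE)
  }
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / (pos_total + neg_total),
    sensitivity = cm$tp / pos_total,
    specificity = cm$tn / neg_total
  )
}

#' @export
print.confusion_binary <- function(x, ...) {
  cat(sprintf("<confusion_binary> positive class: %s\n", attr(x, "positive")))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
    dimnames = list(c("true +", "true -"), c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' @export
as.matrix.confusion_binary <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
    dimnames = list(c("true +", "true -"), c("pred +", "pred -")))
}

#' Multiclass confusion matrix
#'
#' Tallies a C x C count grid (rows: true class, columns: predicted) and
#' derives per-class accuracy (the row-normalized diagonal, i.e. recall)
#' and overall accuracy (trace over total).
#'
#' @param truth,predicted Label vectors of equal length.
#' @param labels Class labels fixing row/column order.
#' @return An object of class `confusion_multiclass`: the count matrix
#'   with attributes; use [multiclass_accuracy()] for the summaries.
#' @export
multiclass_confusion <- function(truth, predicted, labels = unique(truth)) {
  stopifnot(length(truth) == length(predicted))
  truth <- factor(truth, levels = labels)
  predicted <- factor(predicted, levels = labels)
  if (anyNA(truth) || anyNA(predicted)) {
    stop("labels outside the declared class set", call. = FALSE)
  }
  m <- table(truth, predicted)
  structure(unclass(m), class = c("confusion_multiclass", "matrix", "array"))
}

#' @rdname multiclass_confusion
#' @param cm A `confusion_multiclass` object.
#' @export
multiclass_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_multiclass"))
  m <- unclass(cm)
  list(
    overall = sum(diag(m)) / sum(m),
    per_class = diag(m) / rowSums(m)
  )
}
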