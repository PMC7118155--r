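#' Train a pairwise RBF-SVM burn classifier
#'
#' Fits a soft-margin support vector machine with a radial basis function
#' kernel on samples from exactly two classes. The positive class (the
#' null-hypothesis burn group, labeled +1) is the class whose membership
#' the signed decision score asserts. Features are expected to be already
#' normalized with training statistics (see [normalize_features()]);
#' leave-one-out evaluation with per-fold renormalization is provided by
#' [loocv_binary()].
#'
#' When `gamma` is `NULL`, the kernel width defaults to
#' `1 / (n_features * var(X))` with `var(X)` the variance of all training
#' feature entries pooled — a scale-adaptive default; results can be
#' swept by passing `gamma` explicitly.
#'
#' @param features A feature tibble restricted to two labels, with
#'   columns `label` and the feature columns.
#' @param positive_label The label mapped to +1.
#' @param gamma RBF kernel width (default: see Details).
#' @param cost Soft-margin penalty `C` (default 1).
#' @return An object of class `burn_svm` wrapping the fitted machine,
#'   the training feature names and the sign convention of the score.
#' @export
train_svm <- function(features, positive_label, gamma = NULL, cost = 1) {
  feats <- feature_columns(features)
  x <- as.matrix(features[, feats])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  labels <- unique(features$label)
  if (length(labels) != 2L) {
    stop("pairwise training requires exactly two class labels", call. = FALSE)
  }
  if (!positive_label %in% labels) {
    stop(sprintf("positive label '%s' not present in the data", positive_label),
      call. = FALSE)
  }
  negative_label <- setdiff(labels, positive_label)
  if (min(table(features$label)) < 1L) {
    stop("each class must have at least one training sample", call. = FALSE)
  }
  y <- factor(features$label, levels = c(positive_label, negative_label))
  if (is.null(gamma)) gamma <- default_gamma(x)
  fit <- e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = cost,
    scale = FALSE)
  # e1071 orients the decision value toward the first class named in the
  # decision-value column; resolve the sign once so positive scores always
  # mean the positive (null-hypothesis) class.
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  structure(
    list(
      fit = fit, feature_names = feats, gamma = gamma, cost = cost,
      positive_label = positive_label, negative_label = negative_label,
      sign = if (identical(first, positive_label)) 1 else -1
    ),
    class = "burn_svm"
  )
}

# Scale-adaptive RBF width: 1 / (dimension * pooled feature variance).
default_gamma <- function(x) {
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

#' Signed SVM decision score
#'
#' Distance-like signed decision value of a fitted pairwise machine; a
#' positive score predicts the positive (null-hypothesis) class.
#'
#' @param model A [train_svm()] fit.
#' @param samples A feature tibble or matrix whose columns match the
#'   training features.
#' @return Numeric vector of signed scores, one per row.
#' @export
svm_score <- function(model, samples) {
  stopifnot(inherits(model, "burn_svm"))
  x <- as_feature_matrix(samples, model$feature_names)
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
    "decision.values")
  as.numeric(dv[, 1]) * model$sign
}

#' @export
predict.burn_svm <- function(object, newdata, ...) {
  ifelse(svm_score(object, newdata) > 0,
    object$positive_label, object$negative_label)
}

as_feature_matrix <- function(samples, feature_names) {
  if (is.data.frame(samples)) {
    missing_f <- setdiff(feature_names, names(samples))
    if (length(missing_f)) {
      stop(sprintf("samples lack feature column(s): %s",
        paste(missing_f, collapse = ", ")), call. = FALSE)
    }
    samples <- as.matrix(samples[, feature_names, drop = FALSE])
  } else {
    if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
    if (ncol(samples) != length(feature_names)) {
      stop(sprintf("sample dimension %d does not match the %d training features",
        ncol(samples), length(feature_names)), call. = FALSE)
    }
  }
  if (any(!is.finite(samples))) stop("non-finite feature values", call. = FALSE)
  samples
}

#' Leave-one-out cross-validated pairwise classification
#'
#' Independent assessment of the pairwise RBF-SVM: each sample in turn is
#' held out, the min-max normalization statistics and the machine are
#' refit on the remaining samples only (no information leaks from the
#' held-out sample, including through normalization), the held-out sample
#' is transformed with the training-fold ranges and scored, and the
#' predicted-versus-true outcomes are aggregated into a single confusion
#' matrix from which accuracy, sensitivity and specificity are computed.
#'
#' @param features A *raw* (un-normalized) feature tibble with columns
#'   `sample_id` (optional), `label`, and the feature columns, restricted
#'   to two labels with at least two samples each.
#' @inheritParams train_svm
#' @param normalize Refit min-max normalization per fold (default `TRUE`;
#'   set `FALSE` if the features are already on a common scale).
#' @return An object of class `burn_loocv`: list with `confusion`
#'   ([binary_confusion()]), `measures` (tibble), and `scores` (tibble
#'   `sample_id`, `label`, `score`, `predicted`). [tidy()] returns the
#'   per-sample scores, [glance()] the measures.
#' @export
loocv_binary <- function(features, positive_label, gamma = NULL, cost = 1,
                         normalize = TRUE) {
  feats <- feature_columns(features)
  labels <- unique(features$label)
  if (length(labels) != 2L) {
    stop("pairwise LOOCV requires exactly two class labels", call. = FALSE)
  }
  if (min(table(features$label)) < 2L) {
    stop("each class needs at least two samples so every training fold keeps both classes",
      call. = FALSE)
  }
  n <- nrow(features)
  ids <- if ("sample_id" %in% names(features)) features$sample_id else
    sprintf("s%03d", seq_len(n))
  score <- numeric(n)
  for (i in seq_len(n)) {
    train <- features[-i, , drop = FALSE]
    test <- features[i, , drop = FALSE]
    if (normalize) {
      rng <- feature_range(train, feats)
      train <- apply_feature_range(train, rng)
      test <- apply_feature_range(test, rng)
    }
    model <- train_svm(train, positive_label, gamma = gamma, cost = cost)
    score[i] <- svm_score(model, test)
  }
  predicted <- ifelse(score > 0, positive_label, setdiff(labels, positive_label))
  cm <- confusion_from_labels(features$label, predicted, positive_label)
  structure(
    list(
      confusion = cm,
      measures = compute_measures(cm),
      scores = tibble::tibble(sample_id = ids, label = features$label,
        score = score, predicted = predicted),
      positive_label = positive_label
    ),
    class = "burn_loocv"
  )
}

#' @export
print.burn_loocv <- function(x, ...) {
  cat(sprintf(
    "<burn_loocv> positive class %s: accuracy %.3f, sensitivity %.3f, specificity %.3f (n = %d)\n",
    x$positive_label, x$measures$accuracy, x$measures$sensitivity,
    x$measures$specificity, nrow(x$scores)
  ))
  invisible(x)
}

#' @export
tidy.burn_loocv <- function(x, ...) x$scores

#' @export
glance.burn_loocv <- function(x, ...) x$measures

#' @export
autoplot.burn_loocv <- function(object, ...) {
  df <- dplyr::mutate(object$scores, index = dplyr::row_number())
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$index, y = .data$score, colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Sample", y = "SVM decision score",
      title = sprintf("LOOCV scores (positive class: %s)", object$positive_label)
    ) +
    ggplot2::theme_minimal()
}
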