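#' Kernel Fisher discriminant analysis
#'
#' Fits the kernelized Fisher discriminant for `C >= 2` classes with an
#' RBF kernel: in the kernel-induced feature space, find projection
#' directions that maximize the between-class scatter of the projected
#' class means over the within-class scatter. With kernel matrix `K` and
#' per-class column means `m_c` (overall mean `m`), the directions are
#' the leading eigenvectors `alpha` of the generalized problem
#' `M alpha = lambda N alpha`, where
#' `M = sum_c n_c (m_c - m)(m_c - m)'` and
#' `N = sum_c K_c (I - 1/n_c J) K_c' + eps I`; the ridge `eps` is
#' mandatory because the within-class scatter expressed in the kernel
#' basis is rank-deficient. Up to `C - 1` discriminants are returned,
#' ordered by decreasing eigenvalue, giving each sample a score vector
#' `(s1, ..., s_{C-1})`.
#'
#' Classification ([predict.burn_kfda()]) assigns a sample to the class
#' whose training-score centroid is nearest in Euclidean distance in
#' score space; exact ties are broken in favour of the earlier class in
#' the training label order.
#'
#' @param features A feature tibble with a `label` column (>= 2 classes,
#'   each with >= 2 samples) and numeric feature columns, already on a
#'   common scale (e.g. [normalize_features()]).
#' @param gamma RBF kernel width; default `1 / (n_features * var(X))`.
#' @param regularization Ridge `eps` on the within-class scatter;
#'   default `1e-3 * trace(N_within) / n`.
#' @return An object of class `burn_kfda`: training data, kernel width,
#'   discriminant coefficients `alpha` (n x (C-1)), training scores,
#'   class centroids in score space, and the eigenvalues.
#' @export
kfda_fit <- function(features, gamma = NULL, regularization = NULL) {
  feats <- feature_columns(features)
  x <- as.matrix(features[, feats])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- factor(features$label, levels = unique(features$label))
  classes <- levels(y)
  if (length(classes) < 2L) {
    stop("kernel Fisher discriminant analysis needs at least two classes",
      call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("every class needs at least two samples", call. = FALSE)
  }
  n <- nrow(x)
  if (is.null(gamma)) gamma <- default_gamma(x)
  K <- rbf_kernel(x, x, gamma)

  m_all <- rowMeans(K)
  M <- matrix(0, n, n)
  N_within <- matrix(0, n, n)
  for (cl in classes) {
    idx <- which(y == cl)
    n_c <- length(idx)
    K_c <- K[, idx, drop = FALSE]
    m_c <- rowMeans(K_c)
    dm <- m_c - m_all
    M <- M + n_c * tcrossprod(dm)
    centered <- K_c - matrix(m_c, n, n_c) # K_c (I - J/n_c)
    N_within <- N_within + tcrossprod(centered)
  }
  if (is.null(regularization)) {
    regularization <- 1e-3 * sum(diag(N_within)) / n
    if (regularization <= 0) regularization <- 1e-8
  }
  N_reg <- N_within + diag(regularization, n)
  sol <- tryCatch(solve(N_reg, M), error = function(e) {
    stop(paste0(
      "within-class scatter system is singular beyond the current ridge; ",
      "increase `regularization` (currently ", format(regularization), ")"
    ), call. = FALSE)
  })
  eig <- eigen(sol)
  ord <- order(Re(eig$values), decreasing = TRUE)
  n_disc <- length(classes) - 1L
  alpha <- Re(eig$vectors[, ord[seq_len(n_disc)], drop = FALSE])
  # deterministic orientation and scale per discriminant
  for (dcol in seq_len(ncol(alpha))) {
    a <- alpha[, dcol]
    a <- a / sqrt(sum(a^2))
    pivot <- which(abs(a) > 1e-12)[1]
    if (!is.na(pivot) && a[pivot] < 0) a <- -a
    alpha[, dcol] <- a
  }
  scores <- K %*% alpha
  colnames(scores) <- paste0("s", seq_len(n_disc))
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(scores[y == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  structure(
    list(
      x_train = x, y_train = y, classes = classes,
      feature_names = feats, gamma = gamma, regularization = regularization,
      alpha = alpha, eigenvalues = Re(eig$values[ord[seq_len(n_disc)]]),
      scores = scores, centroids = centroids
    ),
    class = "burn_kfda"
  )
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Project samples into discriminant-score space
#'
#' @param model A [kfda_fit()] result.
#' @param samples Feature tibble or matrix matching the training
#'   features.
#' @return Matrix of scores (rows: samples; columns `s1..s_{C-1}`).
#' @export
kfda_scores <- function(model, samples) {
  stopifnot(inherits(model, "burn_kfda"))
  x <- as_feature_matrix(samples, model$feature_names)
  Kx <- rbf_kernel(x, model$x_train, model$gamma) # n_new x n_train
  s <- Kx %*% model$alpha
  colnames(s) <- colnames(model$scores)
  s
}

#' @rdname kfda_scores
#' @param object A [kfda_fit()] result.
#' @param newdata Samples to classify.
#' @param type `"class"` (nearest centroid) or `"scores"`.
#' @param ... Unused.
#' @export
predict.burn_kfda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  s <- kfda_scores(object, newdata)
  if (type == "scores") return(s)
  kfda_classify(object, newdata)
}

#' @rdname kfda_scores
#' @export
kfda_classify <- function(model, samples) {
  s <- kfda_scores(model, samples)
  d2 <- outer(rowSums(s^2), rowSums(model$centroids^2), "+") -
    2 * tcrossprod(s, model$centroids)
  # ties: earlier class in training order wins (max.col with first ties.method
  # on negated distances)
  model$classes[max.col(-d2, ties.method = "first")]
}

#' @export
print.burn_kfda <- function(x, ...) {
  cat(sprintf(
    "<burn_kfda> %d classes, %d discriminants, gamma = %.4g, ridge = %.4g, n = %d\n",
    length(x$classes), ncol(x$alpha), x$gamma, x$regularization, nrow(x$x_train)
  ))
  invisible(x)
}

#' @export
tidy.burn_kfda <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(label = as.character(x$y_train)),
    tibble::as_tibble(x$scores)
  )
}

#' @export
glance.burn_kfda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_discriminants = ncol(x$alpha),
    gamma = x$gamma,
    regularization = x$regularization,
    leading_eigenvalue = x$eigenvalues[1]
  )
}

#' @export
autoplot.burn_kfda <- function(object, ...) {
  df <- tidy(object)
  if (!"s2" %in% names(df)) df$s2 <- 0
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$s1, y = .data$s2, colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Discriminant score s1", y = "Discriminant score s2",
      title = "Kernel Fisher discriminant scores"
    ) +
    ggplot2::theme_minimal()
}

#' Leave-one-out cross-validated multiclass classification
#'
#' Independent assessment of the kernel Fisher discriminant classifier:
#' each sample is held out in turn, normalization and the discriminant
#' are refit on the remaining samples, and the held-out prediction is
#' tallied into a C x C confusion matrix. Per-class accuracy is the
#' row-normalized diagonal (recall); overall accuracy is the number of
#' correctly classified samples over the total.
#'
#' @inheritParams kfda_fit
#' @param normalize Refit per-fold min-max normalization (default `TRUE`).
#' @return An object of class `burn_loocv_mc`: `confusion`
#'   ([multiclass_confusion()]), `overall_accuracy`, `per_class_accuracy`
#'   and the per-sample `predictions` tibble.
#' @export
loocv_multiclass <- function(features, gamma = NULL, regularization = NULL,
                             normalize = TRUE) {
  feats <- feature_columns(features)
  y <- factor(features$label, levels = unique(features$label))
  if (min(table(y)) < 2L) {
    stop("every class needs at least two samples for leave-one-out folds",
      call. = FALSE)
  }
  n <- nrow(features)
  ids <- if ("sample_id" %in% names(features)) features$sample_id else
    sprintf("s%03d", seq_len(n))
  predicted <- character(n)
  for (i in seq_len(n)) {
    train <- features[-i, , drop = FALSE]
    test <- features[i, , drop = FALSE]
    if (normalize) {
      rng <- feature_range(train, feats)
      train <- apply_feature_range(train, rng)
      test <- apply_feature_range(test, rng)
    }
    model <- kfda_fit(train, gamma = gamma, regularization = regularization)
    predicted[i] <- kfda_classify(model, test)
  }
  cm <- multiclass_confusion(features$label, predicted, labels = levels(y))
  acc <- multiclass_accuracy(cm)
  structure(
    list(
      confusion = cm,
      overall_accuracy = acc$overall,
      per_class_accuracy = acc$per_class,
      predictions = tibble::tibble(sample_id = ids, label = features$label,
        predicted = predicted)
    ),
    class = "burn_loocv_mc"
  )
}

#' @export
print.burn_loocv_mc <- function(x, ...) {
  cat(sprintf("<burn_loocv_mc> overall accuracy %.3f over %d samples\n",
    x$overall_accuracy, nrow(x$predictions)))
  print(unclass(x$confusion))
  invisible(x)
}

#' @export
tidy.burn_loocv_mc <- function(x, ...) x$predictions

#' @export
glance.burn_loocv_mc <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall_accuracy,
    n = nrow(x$predictions)
  )
}

#' Monte-Carlo split evaluation of the multiclass classifier
#'
#' Repeatedly splits the data into mutually exclusive training and test
#' sets (stratified per class so no class empties out at small n), fits
#' the kernel Fisher discriminant on the training portion (with
#' training-only normalization) and records the test accuracy. The mean
#' over repetitions estimates the generalization accuracy and should
#' agree closely with the leave-one-out estimate on the same data.
#'
#' @inheritParams loocv_multiclass
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.9).
#' @param repetitions Number of random splits (default 100).
#' @param seed Integer seed driving all splits.
#' @return An object of class `burn_mc`: `mean_accuracy` and a tibble
#'   `accuracies` (`repetition`, `accuracy`).
#' @export
monte_carlo_eval <- function(features, train_fraction = 0.9,
                             repetitions = 100L, seed = 1L,
                             gamma = NULL, regularization = NULL,
                             normalize = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  feats <- feature_columns(features)
  y <- factor(features$label, levels = unique(features$label))
  class_idx <- split(seq_len(nrow(features)), y)
  n_train <- vapply(class_idx, function(ix) round(train_fraction * length(ix)),
    numeric(1))
  if (any(n_train < 2) || any(n_train >= lengths(class_idx))) {
    stop("infeasible split: each class needs >= 2 training and >= 1 test samples",
      call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
    envir = globalenv()))
  set.seed(seed)
  acc <- vapply(seq_len(repetitions), function(rep) {
    train_ix <- sort(unlist(lapply(seq_along(class_idx), function(ci) {
      sample(class_idx[[ci]], n_train[ci])
    }), use.names = FALSE))
    train <- features[train_ix, , drop = FALSE]
    test <- features[-train_ix, , drop = FALSE]
    if (normalize) {
      rng <- feature_range(train, feats)
      train <- apply_feature_range(train, rng)
      test <- apply_feature_range(test, rng)
    }
    model <- kfda_fit(train, gamma = gamma, regularization = regularization)
    mean(kfda_classify(model, test) == test$label)
  }, numeric(1))
  structure(
    list(
      mean_accuracy = mean(acc),
      accuracies = tibble::tibble(repetition = seq_len(repetitions),
        accuracy = acc),
      train_fraction = train_fraction, seed = seed
    ),
    class = "burn_mc"
  )
}

#' @export
print.burn_mc <- function(x, ...) {
  cat(sprintf(
    "<burn_mc> mean accuracy %.3f over %d stratified %.0f/%.0f splits (seed %d)\n",
    x$mean_accuracy, nrow(x$accuracies), 100 * x$train_fraction,
    100 * (1 - x$train_fraction), x$seed
  ))
  invisible(x)
}

#' @export
tidy.burn_mc <- function(x, ...) x$accuracies

#' @export
glance.burn_mc <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = stats::sd(x$accuracies$accuracy),
    repetitions = nrow(x$accuracies)
  )
}
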