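#' Sequential backward feature selection
#'
#' Greedy top-down wrapper selection: starting from the full active
#' feature set, each stage evaluates every single-feature removal with
#' the supplied criterion (by default the mean pairwise leave-one-out
#' cross-validated SVM accuracy over all class pairs, each pair weighted
#' equally) and commits the removal with the highest criterion. The
#' search terminates when the best candidate's criterion falls strictly
#' below the current stage's criterion, i.e. when removing another
#' feature would increase the classification error; removals that leave
#' the criterion unchanged are allowed, favouring smaller sets of
#' non-redundant features. Ties between equal-criterion removals are
#' broken by dropping the feature that comes earliest in the fixed
#' catalog order, which makes the trace deterministic.
#'
#' The criterion is injected as a function `evaluator(feature_names) ->
#' accuracy`, so the search itself is independent of the classifier; the
#' default evaluator is built from `features` via [pairwise_evaluator()].
#'
#' @param features A raw (un-normalized) feature tibble with a `label`
#'   column and >= 2 feature columns.
#' @param class_pairs List of label pairs to average over; `NULL` (the
#'   default) takes all unordered pairs of the labels present, in
#'   first-appearance order.
#' @param evaluator Optional criterion function; see Details.
#' @param gamma,cost RBF-SVM hyperparameters for the default evaluator.
#' @return An object of class `sbs_trace` with elements
#'   * `stages`: tibble (`stage`, `n_features`, `removed`, `criterion`,
#'     list-column `active`), stage 0 being the full set;
#'   * `final_set`: the selected feature names;
#'   * `criterion_curve`: tibble (`n_features`, `criterion`).
#' @export
sbs_select <- function(features, class_pairs = NULL, evaluator = NULL,
                       gamma = NULL, cost = 1) {
  feats <- feature_columns(features)
  if (length(feats) < 2L) {
    stop("sequential backward selection needs at least two active features",
      call. = FALSE)
  }
  if (is.null(evaluator)) {
    evaluator <- pairwise_evaluator(features, class_pairs, gamma = gamma,
      cost = cost)
  }
  eval_subset <- function(subset) {
    tryCatch(evaluator(subset), error = function(e) {
      stop(sprintf("criterion evaluation failed on feature subset {%s}: %s",
        paste(subset, collapse = ", "), conditionMessage(e)), call. = FALSE)
    })
  }

  cur_set <- feats
  cur_crit <- eval_subset(cur_set)
  stages <- list(tibble::tibble(
    stage = 0L, n_features = length(cur_set), removed = NA_character_,
    criterion = cur_crit, active = list(cur_set)
  ))
  stage <- 0L
  while (length(cur_set) >= 2L) {
    cand_crit <- vapply(cur_set, function(f) eval_subset(setdiff(cur_set, f)),
      numeric(1))
    best <- max(cand_crit)
    if (best < cur_crit) break
    removed <- cur_set[which(cand_crit == best)[1]] # earliest in catalog order
    cur_set <- setdiff(cur_set, removed)
    cur_crit <- best
    stage <- stage + 1L
    stages[[stage + 1L]] <- tibble::tibble(
      stage = stage, n_features = length(cur_set), removed = removed,
      criterion = cur_crit, active = list(cur_set)
    )
  }
  stages <- dplyr::bind_rows(stages)
  structure(
    list(
      stages = stages,
      final_set = cur_set,
      criterion_curve = stages[, c("n_features", "criterion")]
    ),
    class = "sbs_trace"
  )
}

#' Mean pairwise LOOCV accuracy criterion
#'
#' Builds the default selection criterion for [sbs_select()]: for a
#' candidate feature subset, run a leave-one-out cross-validated RBF-SVM
#' for every class pair (normalization refit on each training fold) and
#' average the pairwise accuracies with equal weight per pair.
#'
#' @inheritParams sbs_select
#' @return A function `(feature_names) -> mean accuracy`.
#' @export
pairwise_evaluator <- function(features, class_pairs = NULL, gamma = NULL,
                               cost = 1) {
  labels <- unique(features$label)
  if (is.null(class_pairs)) {
    if (length(labels) < 2L) stop("need at least two classes", call. = FALSE)
    class_pairs <- utils::combn(labels, 2L, simplify = FALSE)
  }
  for (pr in class_pairs) {
    if (!all(pr %in% labels)) {
      stop(sprintf("class pair (%s) has labels absent from the data",
        paste(pr, collapse = ", ")), call. = FALSE)
    }
  }
  function(subset) {
    accs <- vapply(class_pairs, function(pr) {
      sub <- features[features$label %in% pr, c("sample_id", "label", subset)]
      res <- loocv_binary(sub, positive_label = pr[2], gamma = gamma, cost = cost)
      glance(res)$accuracy
    }, numeric(1))
    mean(accs)
  }
}

#' @export
print.sbs_trace <- function(x, ...) {
  cat(sprintf(
    "<sbs_trace> %d -> %d features in %d removal stage(s); criterion %.4f -> %.4f\n",
    x$stages$n_features[1], length(x$final_set), nrow(x$stages) - 1L,
    x$stages$criterion[1], x$stages$criterion[nrow(x$stages)]
  ))
  cat("final set:", paste(x$final_set, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.sbs_trace <- function(x, ...) x$stages

#' @export
glance.sbs_trace <- function(x, ...) {
  tibble::tibble(
    n_features_full = x$stages$n_features[1],
    n_features_final = length(x$final_set),
    criterion_full = x$stages$criterion[1],
    criterion_final = x$stages$criterion[nrow(x$stages)]
  )
}

#' @export
autoplot.sbs_trace <- function(object, ...) {
  ggplot2::ggplot(object$criterion_curve,
    ggplot2::aes(x = .data$n_features, y = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = object$criterion_curve$n_features) +
    ggplot2::labs(
      x = "Number of retained features",
      y = "Mean pairwise LOOCV accuracy",
      title = "Sequential backward selection"
    ) +
    ggplot2::theme_minimal()
}

#' Export a selection trace as JSON
#'
#' @param trace An [sbs_select()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sbs_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sbs_trace"))
  payload <- list(
    stages = lapply(seq_len(nrow(trace$stages)), function(r) {
      list(
        stage = trace$stages$stage[r],
        n_features = trace$stages$n_features[r],
        removed = trace$stages$removed[r],
        criterion = trace$stages$criterion[r],
        active = trace$stages$active[[r]]
      )
    }),
    final_set = trace$final_set,
    criterion_curve = trace$criterion_curve
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(path)
}
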