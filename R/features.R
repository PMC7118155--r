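#' Second-order texture feature catalog
#'
#' The catalog holds twenty classical second-order (Haralick-family)
#' statistics of the normalized grey-level co-occurrence matrix. The
#' default active set drops `idn` (inverse difference normalized), giving
#' the nineteen features the burn-classification pipeline extracts per
#' image. With `i, j = 0 .. L-1`, joint probability `p`, marginals
#' `p_x, p_y` (means `mu_x, mu_y`, standard deviations `sigma_x,
#' sigma_y`), sum distribution `p_{x+y}` and difference distribution
#' `p_{x-y}`, the definitions are:
#'
#' | name | definition |
#' |------|-----------|
#' | `autocorrelation` | sum i j p(i,j) |
#' | `cluster_prominence` | sum (i+j-mu_x-mu_y)^4 p(i,j) |
#' | `cluster_shade` | sum (i+j-mu_x-mu_y)^3 p(i,j) |
#' | `contrast` | sum (i-j)^2 p(i,j) |
#' | `correlation` | sum (i-mu_x)(j-mu_y) p(i,j) / (sigma_x sigma_y) |
#' | `difference_entropy` | -sum p_{x-y}(d) log p_{x-y}(d) |
#' | `difference_variance` | variance of p_{x-y} |
#' | `dissimilarity` | sum abs(i-j) p(i,j) |
#' | `energy` | sum p(i,j)^2 |
#' | `entropy` | -sum p(i,j) log p(i,j) |
#' | `homogeneity` | sum p(i,j) / (1+(i-j)^2) |
#' | `imc1` | (HXY - HXY1) / max(HX, HY) |
#' | `imc2` | sqrt(1 - exp(-2 (HXY2 - HXY))) |
#' | `inverse_difference` | sum p(i,j) / (1+abs(i-j)) |
#' | `idmn` | sum p(i,j) / (1+(i-j)^2/L^2) |
#' | `idn` | sum p(i,j) / (1+abs(i-j)/L) |
#' | `maximum_probability` | max p(i,j) |
#' | `sum_average` | sum s p_{x+y}(s) |
#' | `sum_entropy` | -sum p_{x+y}(s) log p_{x+y}(s) |
#' | `sum_variance` | sum (s - sum_average)^2 p_{x+y}(s) |
#'
#' Logarithms are natural throughout, with `0 log 0 := 0` (a global
#' convention; the base cancels inside `imc2` and only rescales the other
#' entropy features). Homogeneity and inverse difference share the same
#' diagonal-similarity form and differ only in the power of the
#' off-diagonal penalty. `difference_variance` is the variance of the
#' difference distribution (one of two definitions in circulation; fixed
#' here globally).
#'
#' @return `glcm_feature_catalog()`: character vector of all twenty
#'   feature names, in the fixed catalog order used for tie-breaking.
#'   `active_features()`: the default nineteen-feature subset.
#' @export
glcm_feature_catalog <- function() {
  c(
    "autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "difference_variance",
    "dissimilarity", "energy", "entropy", "homogeneity", "imc1", "imc2",
    "inverse_difference", "idmn", "idn", "maximum_probability",
    "sum_average", "sum_entropy", "sum_variance"
  )
}

#' @rdname glcm_feature_catalog
#' @export
active_features <- function() {
  setdiff(glcm_feature_catalog(), "idn")
}

#' Compute texture features from a normalized co-occurrence matrix
#'
#' Evaluates the requested catalog features (see
#' [glcm_feature_catalog()]) on a `glcm_prob`. A degenerate matrix whose
#' marginal variance vanishes (constant image) makes `correlation`
#' undefined; it is reported as 0 and the result carries the attribute
#' `degenerate_correlation = TRUE` so batch extraction keeps running.
#'
#' @param p A [normalize_glcm()] or [average_glcm()] result.
#' @param features Character vector of feature names to compute
#'   (default: the active nineteen).
#' @return A named numeric vector, one element per requested feature, in
#'   catalog order.
#' @export
#' @examples
#' img <- grey_image(matrix(c(0, 1, 1, 0), 2, 2), levels = 2)
#' compute_features(normalize_glcm(compute_glcm(img)))
compute_features <- function(p, features = active_features()) {
  stopifnot(inherits(p, "glcm_prob"))
  if (length(features) == 0L) {
    stop("`features` must name at least one catalog feature", call. = FALSE)
  }
  unknown <- setdiff(features, glcm_feature_catalog())
  if (length(unknown)) {
    stop(sprintf(
      "unknown feature name(s): %s\ncatalog: %s",
      paste(unknown, collapse = ", "),
      paste(glcm_feature_catalog(), collapse = ", ")
    ), call. = FALSE)
  }
  features <- intersect(glcm_feature_catalog(), features) # catalog order
  L <- p$levels
  i <- 0:(L - 1L)
  d <- 0:(L - 1L)
  s <- 0:(2L * (L - 1L))
  pd <- p$p_diff
  ps <- p$p_sum
  degenerate <- FALSE

  val <- function(name) {
    switch(name,
      autocorrelation = {
        nz <- which(p$p > 0, arr.ind = TRUE)
        sum((nz[, 1] - 1) * (nz[, 2] - 1) * p$p[nz])
      },
      cluster_prominence = cluster_moment(p, 4),
      cluster_shade = cluster_moment(p, 3),
      contrast = sum(d^2 * pd),
      correlation = {
        if (p$sd_x == 0 || p$sd_y == 0) {
          degenerate <<- TRUE
          0
        } else {
          nz <- which(p$p > 0, arr.ind = TRUE)
          sum((nz[, 1] - 1 - p$mu_x) * (nz[, 2] - 1 - p$mu_y) * p$p[nz]) /
            (p$sd_x * p$sd_y)
        }
      },
      difference_entropy = shannon(pd),
      difference_variance = {
        mu_d <- sum(d * pd)
        sum((d - mu_d)^2 * pd)
      },
      dissimilarity = sum(d * pd),
      energy = sum(p$p^2),
      entropy = p$HXY,
      homogeneity = sum(pd / (1 + d^2)),
      imc1 = {
        hmax <- max(p$HX, p$HY)
        if (hmax == 0) 0 else (p$HXY - p$HXY1) / hmax
      },
      imc2 = sqrt(max(0, 1 - exp(-2 * (p$HXY2 - p$HXY)))),
      inverse_difference = sum(pd / (1 + d)),
      idmn = sum(pd / (1 + d^2 / L^2)),
      idn = sum(pd / (1 + d / L)),
      maximum_probability = max(p$p),
      sum_average = sum(s * ps),
      sum_entropy = shannon(ps),
      sum_variance = {
        sa <- sum(s * ps)
        sum((s - sa)^2 * ps)
      }
    )
  }
  out <- vapply(features, val, numeric(1))
  if (degenerate) attr(out, "degenerate_correlation") <- TRUE
  out
}

cluster_moment <- function(p, power) {
  nz <- which(p$p > 0, arr.ind = TRUE)
  sum(((nz[, 1] - 1) + (nz[, 2] - 1) - p$mu_x - p$mu_y)^power * p$p[nz])
}

#' Extract texture features from a set of images
#'
#' End-to-end per-image feature extraction: co-occurrence matrix at the
#' given offset, probability normalization, then the requested catalog
#' features. Accepts a list of in-memory images, a manifest tibble
#' (columns `path`, `label`) or a manifest CSV path.
#'
#' @param x A list of [grey_image()]s, a manifest tibble, or the path to
#'   a manifest CSV.
#' @param labels Class label per image (list input only; optional).
#' @param offset GLCM offset `c(k, l)` (default horizontal `c(0, 1)`).
#' @param features Catalog features to compute (default the active 19).
#' @param levels Grey-level count used when reading images from a
#'   manifest (default 256).
#' @param ... Passed between methods.
#' @return A tibble with columns `sample_id`, `label` and one numeric
#'   column per feature.
#' @export
extract_features <- function(x, ...) UseMethod("extract_features")

#' @rdname extract_features
#' @export
extract_features.list <- function(x, labels = NULL, offset = c(0L, 1L),
                                  features = active_features(), ...) {
  if (length(x) == 0L) stop("no images supplied", call. = FALSE)
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(x))
  if (is.null(labels)) labels <- NA_character_
  labels <- rep_len(as.character(labels), length(x))
  rows <- purrr::map(x, function(img) {
    fv <- compute_features(normalize_glcm(compute_glcm(img, offset)), features)
    tibble::as_tibble(as.list(fv))
  })
  dplyr::bind_cols(
    tibble::tibble(sample_id = ids, label = labels),
    dplyr::bind_rows(rows)
  )
}

#' @rdname extract_features
#' @export
extract_features.data.frame <- function(x, offset = c(0L, 1L),
                                        features = active_features(),
                                        levels = 256L, ...) {
  x <- as_manifest(tibble::as_tibble(x))
  imgs <- purrr::map(x$path, read_grey_image, levels = levels)
  names(imgs) <- basename(x$path)
  extract_features(imgs, labels = x$label, offset = offset, features = features)
}

#' @rdname extract_features
#' @export
extract_features.character <- function(x, offset = c(0L, 1L),
                                       features = active_features(),
                                       levels = 256L, ...) {
  extract_features(read_manifest(x), offset = offset, features = features,
    levels = levels)
}

# Feature columns of a feature tibble = numeric columns other than ids.
feature_columns <- function(df) {
  setdiff(names(df)[vapply(df, is.numeric, logical(1))],
    c("sample_id", "severity", "seed"))
}

#' Min-max normalize feature columns
#'
#' Maps each feature column independently onto `[0, 1]` by
#' `(x - min(x)) / (max(x) - min(x))`. A constant column maps to all
#' zeros (it carries no discriminative information, and downstream
#' classifiers must still run). The per-column `(min, max)` pair is
#' returned as attribute `"feature_ranges"` so held-out samples can be
#' transformed with training-set statistics via [apply_feature_range()]
#' — the transform is affine and is *not* clipped to `[0, 1]` outside the
#' training range.
#'
#' @param df A feature tibble (e.g. from [extract_features()]) with at
#'   least two rows.
#' @param features Columns to normalize (default: all numeric feature
#'   columns).
#' @return The tibble with normalized feature columns and attribute
#'   `"feature_ranges"` (a tibble `feature`, `min`, `max`).
#' @export
normalize_features <- function(df, features = feature_columns(df)) {
  if (nrow(df) < 2L) {
    stop("min-max normalization needs at least two rows (min = max everywhere is uninformative)",
      call. = FALSE)
  }
  ranges <- feature_range(df, features)
  out <- apply_feature_range(df, ranges)
  attr(out, "feature_ranges") <- ranges
  out
}

#' @rdname normalize_features
#' @export
feature_range <- function(df, features = feature_columns(df)) {
  tibble::tibble(
    feature = features,
    min = vapply(features, function(f) min(df[[f]]), numeric(1), USE.NAMES = FALSE),
    max = vapply(features, function(f) max(df[[f]]), numeric(1), USE.NAMES = FALSE)
  )
}

#' @rdname normalize_features
#' @param ranges A `feature_range()` tibble (typically from the training
#'   fold).
#' @export
apply_feature_range <- function(df, ranges) {
  out <- df
  for (r in seq_len(nrow(ranges))) {
    f <- ranges$feature[r]
    span <- ranges$max[r] - ranges$min[r]
    out[[f]] <- if (span == 0) rep(0, nrow(df)) else (df[[f]] - ranges$min[r]) / span
  }
  out
}

#' Per-class feature means and severity trends
#'
#' Normalizes each feature over the full sample (min-max to `[0, 1]`),
#' averages it within each class, and reports the direction of the trend
#' across an ordered severity ladder as the sign of the Spearman
#' correlation between the class means and the class rank. Used to check
#' the expected texture evolution with burn severity: contrast,
#' difference variance, the second information measure of correlation and
#' sum entropy grow as speckle spreads the co-occurrence mass off the
#' diagonal, while correlation, homogeneity, inverse difference and
#' maximum probability shrink.
#'
#' @param df A raw feature tibble with a `label` column.
#' @param class_order Character vector giving the class labels in
#'   increasing severity order (>= 2 classes, all present in `df`).
#' @param features Features to report (default: all feature columns).
#' @return A tibble with one row per feature: the per-class mean of the
#'   normalized values (one column per class, in `class_order`), the
#'   Spearman correlation `rho`, and `trend` (its sign: -1, 0 or 1).
#' @export
feature_trend_report <- function(df, class_order,
                                 features = feature_columns(df)) {
  if (length(class_order) < 2L) {
    stop("`class_order` must list at least two classes", call. = FALSE)
  }
  missing_cls <- setdiff(class_order, df$label)
  if (length(missing_cls)) {
    stop(sprintf("class(es) not present in the data: %s",
      paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  df <- dplyr::filter(df, .data$label %in% class_order)
  norm <- normalize_features(df, features)
  long <- tidyr::pivot_longer(
    norm[, c("label", features)],
    cols = dplyr::all_of(features), names_to = "feature", values_to = "value"
  )
  means <- long |>
    dplyr::group_by(.data$feature, .data$label) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "label", values_from = "mean")
  wide <- wide[match(features, wide$feature), c("feature", class_order)]
  rank_sev <- seq_along(class_order)
  rho <- vapply(seq_len(nrow(wide)), function(r) {
    m <- as.numeric(wide[r, class_order])
    if (stats::sd(m) == 0) 0 else stats::cor(m, rank_sev, method = "spearman")
  }, numeric(1))
  dplyr::mutate(wide, rho = rho, trend = sign(rho))
}
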