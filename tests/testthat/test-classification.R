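two_cluster_1d <- function() {
  tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    label = c("left", "left", "right", "right"),
    f = c(0, 0.1, 0.9, 1.0)
  )
}

test_that("separable clusters train to a correctly signed decision function", {
  df <- two_cluster_1d()
  m <- train_svm(df, positive_label = "left")
  expect_equal(unname(predict(m, df)), df$label)
  expect_gt(svm_score(m, tibble::tibble(f = 0.05)), 0)
  expect_lt(svm_score(m, tibble::tibble(f = 0.95)), 0)
  # the sign convention follows the declared positive class
  m2 <- train_svm(df, positive_label = "right")
  expect_lt(svm_score(m2, tibble::tibble(f = 0.05)), 0)
  expect_gt(svm_score(m2, tibble::tibble(f = 0.95)), 0)
})

test_that("the RBF kernel separates the XOR pattern a linear machine cannot", {
  df <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    label = rep(c("same", "diff"), each = 4),
    x = c(0, 0, 1, 1, 0, 0, 1, 1),
    y = c(0, 0, 1, 1, 1, 1, 0, 0)
  )
  df$x <- df$x + rep(c(0, 0.02), 4) # duplicate-free jitter, pattern intact
  m <- train_svm(df, positive_label = "same", gamma = 10, cost = 100)
  expect_equal(unname(predict(m, df)), df$label)
})

test_that("identical points in both classes do not crash training", {
  df <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    label = c("a", "a", "b", "b"),
    f = c(0.5, 0.2, 0.5, 0.8)
  )
  m <- train_svm(df, positive_label = "a")
  acc <- mean(predict(m, df) == df$label)
  expect_lte(acc, 1)
  expect_gte(acc, 0.5)
})

test_that("decision scores are continuous in the input", {
  df <- two_cluster_1d()
  m <- train_svm(df, positive_label = "left")
  x0 <- tibble::tibble(f = 0.4)
  for (delta in c(1e-3, 1e-4)) {
    x1 <- tibble::tibble(f = 0.4 + delta)
    expect_lt(abs(svm_score(m, x1) - svm_score(m, x0)), 50 * delta)
  }
})

test_that("feature dimension and name mismatches are rejected", {
  df <- two_cluster_1d()
  m <- train_svm(df, positive_label = "left")
  expect_error(svm_score(m, tibble::tibble(g = 1)), "lack feature")
  expect_error(svm_score(m, matrix(1:4, 1)), "dimension")
  df_bad <- df; df_bad$f[1] <- NA
  expect_error(train_svm(df_bad, "left"), "non-finite")
})

test_that("pairwise LOOCV is perfect on well-separated classes and order-invariant", {
  set.seed(77)
  df <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:16),
    label = rep(c("lo", "hi"), each = 8),
    f1 = c(rnorm(8, 0, 0.05), rnorm(8, 1, 0.05)),
    f2 = c(rnorm(8, 1, 0.05), rnorm(8, 0, 0.05))
  )
  res <- loocv_binary(df, positive_label = "hi")
  expect_equal(glance(res)$accuracy, 1)
  expect_equal(res$confusion$tp + res$confusion$tn + res$confusion$fp +
    res$confusion$fn, 16)

  perm <- sample(nrow(df))
  res2 <- loocv_binary(df[perm, ], positive_label = "hi")
  expect_equal(as.matrix(res2$confusion), as.matrix(res$confusion))
  s1 <- res$scores[order(res$scores$sample_id), ]
  s2 <- res2$scores[order(res2$scores$sample_id), ]
  expect_equal(s2$predicted, s1$predicted)
  # the margin optimizer converges to row-order-dependent numerical noise;
  # the decision values must agree to optimizer tolerance, the labels exactly
  expect_equal(s2$score, s1$score, tolerance = 1e-2)

  df_small <- df[c(1, 9, 10), ]
  expect_error(loocv_binary(df_small, positive_label = "hi"),
    "at least two samples")
})

test_that("confusion-matrix measures reproduce their defining ratios", {
  perfect <- compute_measures(binary_confusion(tp = 34, fn = 0, fp = 0, tn = 37))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  mixed <- compute_measures(binary_confusion(tp = 36, fn = 3, fp = 2, tn = 35))
  expect_equal(mixed$accuracy, 71 / 76)
  expect_equal(mixed$sensitivity, 36 / 39)
  expect_equal(mixed$specificity, 35 / 37)
  expect_equal(round(as.numeric(mixed), 2), c(0.93, 0.92, 0.95))

  allneg <- compute_measures(binary_confusion(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_equal(as.numeric(allneg), c(0.5, 0, 1))

  expect_error(compute_measures(binary_confusion(0, 0, 2, 3)), "both classes")
  expect_error(binary_confusion(-1, 0, 0, 0), "non-negative")
})

test_that("multiclass confusion summaries are row-normalized recall and trace accuracy", {
  truth <- rep(c("a", "b", "c"), each = 4)
  pred <- truth; pred[1] <- "b" # one off-diagonal count
  cm <- multiclass_confusion(truth, pred, labels = c("a", "b", "c"))
  acc <- multiclass_accuracy(cm)
  expect_equal(acc$overall, 11 / 12)
  expect_equal(unname(acc$per_class), c(3 / 4, 1, 1))
  expect_error(multiclass_confusion(truth, c(pred[-1], "zzz"), c("a", "b", "c")),
    "outside")
})

test_that("the diagnostic sample-size bound evaluates both branches with a ceiling", {
  expect_identical(min_sample_size(0.95, 0.95, prevalence = 0.4, margin = 0.1,
    z = 1.96), 46L)
  # 1.96^2 * 0.09 / (0.01 * 0.5) = 69.1488 -> 70
  expect_identical(min_sample_size(0.9, 0.9, prevalence = 0.5, margin = 0.1,
    z = 1.96), 70L)
  expect_identical(min_sample_size(1, 1, prevalence = 0.5, margin = 0.1), 0L)
  expect_error(min_sample_size(0.95, 0.95, prevalence = 0, margin = 0.1),
    "prevalence")
  expect_error(min_sample_size(0.95, 0.95, prevalence = 1, margin = 0.1),
    "prevalence")
  expect_error(min_sample_size(0.95, 0.95, prevalence = 0.4, margin = 0),
    "margin")

  # monotone: non-increasing in the margin, non-decreasing in z
  ds <- c(0.05, 0.1, 0.2, 0.4)
  ns <- vapply(ds, function(d) min_sample_size(0.9, 0.85, 0.4, d, z = 1.96),
    integer(1))
  expect_true(all(diff(ns) <= 0))
  zs <- c(1.28, 1.64, 1.96, 2.58)
  nz <- vapply(zs, function(z) min_sample_size(0.9, 0.85, 0.4, 0.1, z = z),
    integer(1))
  expect_true(all(diff(nz) >= 0))
})
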