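prob_from_matrix <- function(pm) {
  burntex:::glcm_prob_from_p(pm, levels = nrow(pm))
}

test_that("hand-computed feature values on tiny probability matrices", {
  # degenerate single-cell distribution
  p1 <- prob_from_matrix(matrix(c(1, 0, 0, 0), 2, 2))
  f1 <- compute_features(p1, c("contrast", "energy", "maximum_probability",
    "sum_entropy", "homogeneity"))
  expect_equal(f1[["contrast"]], 0)
  expect_equal(f1[["energy"]], 1)
  expect_equal(f1[["maximum_probability"]], 1)
  expect_equal(f1[["sum_entropy"]], 0)
  expect_equal(f1[["homogeneity"]], 1)

  # perfectly correlated diagonal
  p2 <- prob_from_matrix(diag(2) / 2)
  f2 <- compute_features(p2, c("correlation", "contrast", "energy"))
  expect_equal(f2[["correlation"]], 1)
  expect_equal(f2[["contrast"]], 0)
  expect_equal(f2[["energy"]], 0.5)

  # uniform 2x2: homogeneity 0.25 (1 + 1/2 + 1/2 + 1) = 0.75, contrast 0.5
  p3 <- prob_from_matrix(matrix(0.25, 2, 2))
  f3 <- compute_features(p3, c("homogeneity", "contrast"))
  expect_equal(f3[["homogeneity"]], 0.75)
  expect_equal(f3[["contrast"]], 0.5)
})

test_that("every catalog feature matches the brute-force oracle on random matrices", {
  set.seed(404)
  for (rep in 1:25) {
    pm <- random_prob_matrix(4)
    got <- compute_features(prob_from_matrix(pm), glcm_feature_catalog())
    want <- oracle_features(pm)
    expect_equal(got[names(want)], want, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # and on a sparse matrix with empty rows/columns
  pm <- matrix(0, 4, 4); pm[1, 2] <- 0.6; pm[3, 3] <- 0.4
  got <- compute_features(prob_from_matrix(pm), glcm_feature_catalog())
  expect_equal(got[names(oracle_features(pm))], oracle_features(pm),
    tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("feature ranges respect their analytic bounds", {
  set.seed(99)
  for (rep in 1:15) {
    pm <- random_prob_matrix(sample(2:6, 1))
    f <- compute_features(prob_from_matrix(pm), glcm_feature_catalog())
    expect_gte(f[["energy"]], 0); expect_lte(f[["energy"]], 1)
    expect_gte(f[["maximum_probability"]], 0)
    expect_lte(f[["maximum_probability"]], 1)
    expect_gte(f[["correlation"]], -1); expect_lte(f[["correlation"]], 1)
    expect_gt(f[["homogeneity"]], 0); expect_lte(f[["homogeneity"]], 1)
    expect_gt(f[["inverse_difference"]], 0)
    expect_lte(f[["inverse_difference"]], 1)
    expect_gte(f[["contrast"]], 0)
    expect_gte(f[["entropy"]], 0)
    expect_gte(f[["sum_entropy"]], 0)
    expect_gte(f[["difference_entropy"]], 0)
    expect_gte(f[["imc2"]], 0); expect_lt(f[["imc2"]], 1)
  }
})

test_that("contrast vanishes exactly on diagonal matrices and only there", {
  set.seed(8)
  dg <- diag(stats::rexp(5)); dg <- dg / sum(dg)
  expect_equal(compute_features(prob_from_matrix(dg), "contrast")[["contrast"]], 0)
  offd <- matrix(0, 3, 3); offd[1, 2] <- 1
  expect_gt(compute_features(prob_from_matrix(offd), "contrast")[["contrast"]], 0)
})

test_that("grey-value permutation preserves distributional features but not geometric ones", {
  set.seed(55)
  img <- random_image(10, 10, 4)
  perm <- c(2L, 0L, 3L, 1L) # relabel grey values
  img_p <- grey_image(matrix(perm[unclass(img) + 1L], nrow(img)), levels = 4)
  f <- compute_features(normalize_glcm(compute_glcm(img)),
    c("energy", "entropy", "maximum_probability", "contrast", "correlation"))
  fp <- compute_features(normalize_glcm(compute_glcm(img_p)),
    c("energy", "entropy", "maximum_probability", "contrast", "correlation"))
  expect_equal(fp[["energy"]], f[["energy"]], tolerance = 1e-12)
  expect_equal(fp[["entropy"]], f[["entropy"]], tolerance = 1e-12)
  expect_equal(fp[["maximum_probability"]], f[["maximum_probability"]])
  expect_false(isTRUE(all.equal(fp[["contrast"]], f[["contrast"]])))
  expect_false(isTRUE(all.equal(fp[["correlation"]], f[["correlation"]])))
})

test_that("constant images flag the degenerate correlation instead of crashing", {
  flat <- grey_image(matrix(3L, 4, 4), levels = 8)
  f <- compute_features(normalize_glcm(compute_glcm(flat)), c("correlation"))
  expect_equal(f[["correlation"]], 0)
  expect_true(attr(f, "degenerate_correlation"))
})

test_that("unknown feature names fail with the catalog listed", {
  p <- prob_from_matrix(matrix(0.25, 2, 2))
  expect_error(compute_features(p, "glrlm_sre"), "catalog")
  expect_error(compute_features(p, character(0)), "at least one")
})

test_that("min-max normalization maps columns onto [0,1] with leak-free reuse", {
  df <- tibble::tibble(
    sample_id = c("a", "b", "c"), label = c("x", "x", "y"),
    f1 = c(2, 4, 6), f2 = c(5, 5, 5), f3 = c(-1, 0, 3)
  )
  norm <- normalize_features(df)
  expect_equal(norm$f1, c(0, 0.5, 1))
  expect_equal(norm$f2, c(0, 0, 0)) # constant column, by convention
  expect_equal(norm$f3, c(0, 0.25, 1))

  rng <- attr(norm, "feature_ranges")
  held_out <- tibble::tibble(sample_id = "d", label = "y",
    f1 = 8, f2 = 5, f3 = -3)
  ho <- apply_feature_range(held_out, rng)
  expect_equal(ho$f1, 1.5) # outside [0,1]: not clipped
  expect_equal(ho$f2, 0)
  expect_equal(ho$f3, -0.5)

  expect_error(normalize_features(df[1, ]), "at least two rows")
})

test_that("trend report recovers the direction of monotone class means", {
  df <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    label = rep(c("lo", "mid", "hi"), each = 2),
    up = c(0.1, 0.1, 0.5, 0.5, 0.9, 0.9),
    down = c(0.9, 0.9, 0.5, 0.5, 0.1, 0.1),
    flat = c(1, 2, 1, 2, 1, 2)
  )
  tr <- feature_trend_report(df, c("lo", "mid", "hi"))
  expect_equal(tr$trend[tr$feature == "up"], 1)
  expect_equal(tr$trend[tr$feature == "down"], -1)
  expect_equal(tr$trend[tr$feature == "flat"], 0)
  expect_equal(tr$lo[tr$feature == "up"], 0)
  expect_equal(tr$hi[tr$feature == "up"], 1)

  # identical classes: every trend is zero
  df2 <- df
  df2$up <- rep(c(0.2, 0.8), 3); df2$down <- rep(c(0.2, 0.8), 3)
  tr2 <- feature_trend_report(df2, c("lo", "mid", "hi"))
  expect_true(all(tr2$trend == 0))

  expect_error(feature_trend_report(df, c("lo", "nope")), "not present")
})
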