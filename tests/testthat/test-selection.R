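# A stub feature table whose columns drive evaluator-based tests; the
# label column is unused by stub evaluators but keeps the interface.
stub_features <- function(feature_names, n = 4) {
  df <- tibble::tibble(
    sample_id = sprintf("s%d", seq_len(n)),
    label = rep(c("A", "B"), length.out = n)
  )
  for (f in feature_names) df[[f]] <- stats::runif(n)
  df
}

test_that("a redundant feature is dropped and the search keeps the better subset", {
  set.seed(1)
  df <- stub_features(c("fA", "fB"))
  acc <- function(subset) {
    key <- paste(sort(subset), collapse = "+")
    c("fA" = 1.0, "fB" = 0.8, "fA+fB" = 0.9)[[key]]
  }
  tr <- sbs_select(df, evaluator = acc)
  expect_equal(tr$stages$removed[2], "fB")
  expect_equal(tr$final_set, "fA")
  expect_equal(tr$stages$criterion, c(0.9, 1.0))
})

test_that("equal-criterion ties remove features in catalog order down to one", {
  set.seed(2)
  df <- stub_features(c("contrast", "correlation", "energy", "entropy"))
  tr <- sbs_select(df, evaluator = function(subset) 0.75)
  expect_equal(tr$stages$removed[-1], c("contrast", "correlation", "energy"))
  expect_equal(tr$final_set, "entropy")
  expect_true(all(tr$stages$criterion == 0.75))
})

test_that("the search terminates when any removal would increase the error", {
  set.seed(3)
  df <- stub_features(c("f1", "f2", "f3"))
  acc <- function(subset) length(subset) / 10 # larger sets always better
  tr <- sbs_select(df, evaluator = acc)
  expect_equal(nrow(tr$stages), 1L)
  expect_equal(sort(tr$final_set), c("f1", "f2", "f3"))
})

test_that("greedy selection is bracketed by the exhaustive-search optimum", {
  set.seed(4)
  feats <- c("f1", "f2", "f3", "f4", "f5")
  df <- stub_features(feats)
  # fixed random utility per feature with redundancy penalty: submodular-ish
  # but arbitrary enough that greedy need not find the optimum
  util <- c(f1 = 0.31, f2 = 0.27, f3 = 0.22, f4 = 0.18, f5 = 0.25)
  pair_penalty <- function(s) 0.06 * choose(length(s), 2)
  acc <- function(subset) {
    max(util[subset]) + 0.3 * mean(util[subset]) - pair_penalty(subset)
  }
  tr <- sbs_select(df, evaluator = acc)
  all_subsets <- unlist(lapply(1:5, function(k) {
    utils::combn(feats, k, simplify = FALSE)
  }), recursive = FALSE)
  brute <- vapply(all_subsets, acc, numeric(1))
  final_crit <- tr$stages$criterion[nrow(tr$stages)]
  expect_gte(final_crit, acc(feats))          # never worse than the full set
  expect_lte(final_crit, max(brute) + 1e-12)  # never beats the global optimum
})

test_that("the criterion curve never decreases through the final stage", {
  set.seed(6)
  ds <- generate_dataset(severities = c(0.15, 0.85), n_per_class = 6, seed = 11,
    height = 48L, width = 48L)
  ft <- extract_features(ds$images, labels = ds$manifest$label,
    features = c("contrast", "correlation", "homogeneity", "sum_entropy"))
  tr <- sbs_select(ft)
  expect_true(all(diff(tr$stages$criterion) >= 0))
  expect_gte(tr$stages$criterion[nrow(tr$stages)], tr$stages$criterion[1])
  expect_true(all(vapply(seq_len(nrow(tr$stages) - 1), function(s) {
    setdiff(tr$stages$active[[s]], tr$stages$active[[s + 1]]) ==
      tr$stages$removed[s + 1]
  }, logical(1))))
})

test_that("sample order does not change the selection trace", {
  set.seed(12)
  ds <- generate_dataset(severities = c(0.2, 0.8), n_per_class = 5, seed = 21,
    height = 40L, width = 40L)
  ft <- extract_features(ds$images, labels = ds$manifest$label,
    features = c("contrast", "homogeneity", "energy"))
  tr1 <- sbs_select(ft)
  perm <- sample(nrow(ft))
  tr2 <- sbs_select(ft[perm, ])
  expect_equal(tr1$stages$removed, tr2$stages$removed)
  expect_equal(tr1$stages$criterion, tr2$stages$criterion)
  expect_equal(tr1$final_set, tr2$final_set)
})

test_that("evaluator failures name the offending subset", {
  set.seed(9)
  df <- stub_features(c("g1", "g2"))
  boom <- function(subset) {
    if (identical(subset, "g1")) stop("numerical collapse")
    0.5
  }
  expect_error(sbs_select(df, evaluator = boom), "g1")
})

test_that("traces export to JSON and summarize via tidy/glance", {
  set.seed(10)
  df <- stub_features(c("h1", "h2", "h3"))
  tr <- sbs_select(df, evaluator = function(subset) 0.6)
  g <- glance(tr)
  expect_equal(g$n_features_full, 3L)
  expect_equal(g$n_features_final, 1L)
  expect_s3_class(tidy(tr), "tbl_df")
  f <- withr::local_tempfile(fileext = ".json")
  write_sbs_trace(tr, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$final_set[[1]], tr$final_set)
  expect_length(back$stages, nrow(tr$stages))
})
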