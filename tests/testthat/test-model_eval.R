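test_that("every classifier configuration trains and scores in [0, 1]", {
  x <- toy_feature_matrix(n = 60)
  y <- attr(x, "labels")
  xm <- unclass(x)[, ]
  for (name in CLASSIFIER_NAMES) {
    cfg <- classifier_config(name)
    set.seed(7)
    model <- cfg$fit(xm, y)
    scores <- cfg$score(model, xm)
    expect_length(scores, nrow(xm))
    expect_true(all(scores >= 0 & scores <= 1),
                label = paste(name, "scores within [0,1]"))
    # separable training data: every learner beats chance in-sample
    expect_gt(auc(scores, y), 0.6)
  }
})

test_that("stratified folds keep both classes in every fold", {
  set.seed(91)
  y <- c(rep(1, 12), rep(0, 88))
  f <- stratified_folds(y, 10)
  for (k in unique(f)) {
    expect_true(any(y[f == k] == 1))
    expect_true(any(y[f == k] == 0))
  }
  # minority class smaller than folds: folds reduced with a warning
  y2 <- c(rep(1, 4), rep(0, 40))
  expect_warning(f2 <- stratified_folds(y2, 10), "reducing folds")
  expect_identical(max(f2), 4L)
  expect_error(stratified_folds(c(1, rep(0, 10)), 5), "degenerate")
})

test_that("cross-validation is reproducible and leaves global RNG usable", {
  x <- toy_feature_matrix(n = 60)
  cfg <- classifier_config("DT")
  a <- run_cv(x, cfg, folds = 5, repeats = 2, seed = 3)
  b <- run_cv(x, cfg, folds = 5, repeats = 2, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- run_cv(x, cfg, folds = 5, repeats = 2, seed = 4)
  expect_false(identical(as.data.frame(a), as.data.frame(d)))
  expect_true(all(a$accuracy >= 0 & a$accuracy <= 100))
  expect_true(all(is.na(a$auc) | (a$auc >= 0 & a$auc <= 1)))
})

test_that("per-fold feature selection restricts the classifier's view", {
  x <- toy_feature_matrix(n = 60)
  cv <- run_cv(x, classifier_config("DT"), folds = 5, repeats = 1,
               seed = 3, select_fraction = 0.4)
  expect_true(all(cv$n_features <= ceiling(0.4 * ncol(x))))
  cv_glob <- run_cv(x, classifier_config("DT"), folds = 5, repeats = 1,
                    seed = 3, select_fraction = 0.4,
                    selection_mode = "global")
  expect_true(all(cv_glob$n_features <= ceiling(0.4 * ncol(x))))
})

test_that("the Friedman statistic matches closed forms", {
  # strict ordering, k = 3, N = 4: rank sums 4/8/12 give exactly 8
  perf <- matrix(rep(c(3, 2, 1), 4), nrow = 4, byrow = TRUE)
  ft <- friedman_test(perf)
  expect_equal(ft$statistic, 8)
  expect_equal(unname(ft$avg_ranks), c(1, 2, 3))
  expect_equal(ft$p_value, pchisq(8, 2, lower.tail = FALSE))

  # identical columns: statistic 0, all average ranks (k+1)/2
  tied <- matrix(5, nrow = 3, ncol = 4)
  ft0 <- friedman_test(tied)
  expect_equal(ft0$statistic, 0)
  expect_equal(unname(ft0$avg_ranks), rep(2.5, 4))

  # permuting dataset rows changes nothing
  set.seed(101)
  perf2 <- matrix(rnorm(24), nrow = 6)
  expect_equal(friedman_test(perf2)$statistic,
               friedman_test(perf2[sample(6), ])$statistic)
  # per-dataset ranks always sum to k(k+1)/2
  expect_true(all(rowSums(friedman_test(perf2)$ranks) == 10))
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("Friedman agrees with the stats implementation on untied data", {
  set.seed(111)
  perf <- matrix(rnorm(40), nrow = 8, ncol = 5)
  ours <- friedman_test(perf)
  ref <- stats::friedman.test(perf)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Bergmann-Hommel adjustment has the right structure", {
  # a single pair is returned untouched
  expect_identical(bergman_hommel(0.03, k = 2), 0.03)
  # all raw p-values 1 stay 1
  expect_equal(bergman_hommel(rep(1, 6), k = 4), rep(1, 6))
  # k = 3 worked case against the enumeration oracle
  p <- c(0.01, 0.02, 0.5)
  expect_equal(bergman_hommel(p, k = 3), bergman_hommel_oracle(p, 3),
               tolerance = 1e-12)
  expect_true(all(bergman_hommel(p, 3) >= p))
  expect_true(all(bergman_hommel(p, 3) <= 1))
  expect_error(bergman_hommel(c(0.1, 0.2), k = 3), "expected 3")
  expect_warning(adj <- bergman_hommel(runif(45), k = 10), "Holm")
  expect_length(adj, 45)
})

test_that("exhaustive sets follow the partition structure", {
  s3 <- exhaustive_sets(3)
  expect_length(s3, 4)  # three single pairs plus the full triangle
  expect_true(any(vapply(s3, identical, logical(1), 1:3)))
  s4 <- exhaustive_sets(4)
  expect_length(s4, 14)
  oracle <- exhaustive_sets_oracle(4)
  norm <- function(l) unique(lapply(l, sort))
  expect_setequal(lapply(norm(s4), paste, collapse = ","),
                  lapply(norm(oracle), paste, collapse = ","))
})

test_that("comparison tables assemble ranks, test and post-hoc", {
  set.seed(121)
  perf <- matrix(runif(15, 0.5, 1), nrow = 5, ncol = 3,
                 dimnames = list(NULL, c("M", "C", "M+C")))
  ct <- compare_configurations(perf, metric = "AUC")
  expect_s3_class(ct, "comparison_table")
  expect_equal(sum(ct$avg_ranks), 6)  # k = 3: ranks sum to 6 per dataset
  expect_identical(nrow(ct$pairwise), 3L)
  expect_true(all(ct$pairwise$p_bergmann_hommel <=
                    ct$pairwise$p_holm + 1e-12))
  expect_output(print(ct), "Friedman")
})
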