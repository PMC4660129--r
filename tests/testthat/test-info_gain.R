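test_that("entropy matches the discrete formula", {
  expect_equal(entropy(c(1, 1, 1)), 0)
  expect_equal(entropy(c(0, 1, 0, 1)), 1)
  expect_equal(entropy(c(1, 1, 1, 0)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))  # 0.8113
  expect_equal(entropy(c("a", "b", "c", "d")), 2)
  expect_error(entropy(integer()), "empty")
})

test_that("information gain reproduces hand-computed and limiting cases", {
  y <- c(1, 1, 1, 0, 0, 0)
  # perfect predictor attains the class entropy
  expect_equal(information_gain(y, y), entropy(y))
  # constant feature is uninformative
  expect_equal(information_gain(rep(1, 6), y), 0)
  f <- c(1, 1, 0, 0, 0, 0)
  expect_equal(information_gain(f, y), 1 - 4 / 6 * entropy(c(1, 0, 0, 0)),
               tolerance = 1e-12)  # 0.4591
  expect_error(information_gain(1:3, 1:4), "length")
})

test_that("gain is bounded by class entropy and invariant to relabeling", {
  set.seed(51)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    f <- sample(1:4, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    ig <- information_gain(f, y)
    expect_gte(ig, -1e-12)
    expect_lte(ig, entropy(y) + 1e-12)
    relabeled <- c(40, 7, 19, 2)[f]
    expect_equal(information_gain(relabeled, y), ig, tolerance = 1e-12)
  }
})

test_that("equal-frequency discretization balances occupancy and keeps binaries", {
  expect_identical(discretize(c(0, 1, 1, 0, 1)), c(1L, 2L, 2L, 1L, 2L))
  expect_identical(discretize(rep(3.7, 8)), rep(1L, 8))
  set.seed(61)
  for (rep in 1:20) {
    x <- rnorm(100)  # distinct values almost surely
    bins <- sample(2:10, 1)
    d <- discretize(x, bins)
    occ <- table(d)
    expect_lte(max(occ) - min(occ), 1)
    expect_identical(length(occ), as.integer(bins))
  }
  expect_error(discretize(1:5, 1), ">= 2")
})

test_that("rankings are sorted, deterministic, and selections are nested", {
  x <- toy_feature_matrix()
  rk <- rank_features(x)
  expect_identical(rk$rank, seq_len(ncol(x)))
  expect_true(all(diff(rk$gain_bits) <= 1e-12))
  expect_true(all(rk$gain_bits >= -1e-12))
  expect_lte(max(rk$gain_bits), attr(rk, "class_entropy") + 1e-12)
  expect_identical(rank_features(x)$feature, rk$feature)

  expect_identical(select_top_fraction(rk, 1), rk$feature)
  expect_identical(select_top_fraction(rk, 0.1), rk$feature[1])
  prev <- character()
  for (fr in selection_grid()) {
    cur <- select_top_fraction(rk, fr)
    expect_identical(length(cur), as.integer(ceiling(fr * ncol(x))))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(select_top_fraction(rk, 0), "fraction")
  expect_error(select_top_fraction(rk, 1.2), "fraction")
})
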