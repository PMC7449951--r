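# Trees and ensembles: prediction, conditional expectations, trainers,
# serialization, adapter.

test_that("ensemble prediction follows the aggregation rule", {
  stump <- make_stump()
  expect_equal(predict(tree_ensemble(list(stump)), 1), 20)
  expect_equal(predict(tree_ensemble(list(stump)), 0), 10)
  two <- tree_ensemble(list(stump, stump), weights = 0.5)
  expect_equal(predict(two, 0), 10)
  empty <- tree_ensemble(list(), base_offset = 7.7)
  expect_equal(predict(empty, c(0, 1)), 7.7)
  expect_error(predict(tree_ensemble(list(make_stump(f = 3))), c(1)),
               "feature index")
})

test_that("conditional expectation reduces to prediction and cover means", {
  stump <- make_stump()
  expect_equal(conditional_expectation(stump, 1, 1L), 20)
  expect_equal(conditional_expectation(stump, 1, integer(0)), 15)
  # hand recursion on a 4-leaf tree, S = {feature 2} (0-based feature 1),
  # x = (0.3, 0.8): feature 2 follows the right branch everywhere, feature 1
  # is averaged by cover: (40 * 2 + 60 * 4) / 100
  tr <- make_depth2_tree(covers = c(10, 30, 25, 35), values = c(1, 2, 3, 4))
  expect_equal(conditional_expectation(tr, c(0.3, 0.8), 2L),
               (40 * 2 + 60 * 4) / 100)
  # full conditioning equals prediction on random trees
  for (s in 1:10) {
    rt <- random_tree(6, 3, rng_seed = s)
    x <- stats::runif(6)
    expect_equal(conditional_expectation(rt, x, 1:6),
                 shapfp:::predict_tree(rt, x), tolerance = 1e-12)
  }
})

test_that("exhaustive tree fitting finds a perfectly separating bit", {
  # six rows, y separated exactly by bit 3 (0-based) = column 4
  X <- matrix(0, 6, 6)
  X[, 4] <- c(1, 1, 1, 0, 0, 0)
  X[, 2] <- c(1, 0, 1, 0, 1, 0)   # uninformative decoy
  y <- c(5, 5, 5, 1, 1, 1)
  tr <- fit_tree(X, y, max_depth = 1)
  expect_identical(tr$feature[1], 4L)
  expect_equal(shapfp:::predict_tree_matrix(tr, X), y)
})

test_that("depth-0 trees and constant responses give single leaves", {
  X <- matrix(stats::runif(20), 10, 2)
  tr0 <- fit_tree(X, stats::runif(10), max_depth = 0)
  expect_length(tr0$feature, 1L)
  expect_true(is.na(tr0$feature[1]))
  trc <- fit_tree(X, rep(3.3, 10), max_depth = 5)
  expect_length(trc$feature, 1L)
  expect_equal(trc$value[1], 3.3)
})

test_that("random-threshold fitting is deterministic per seed", {
  set.seed(1)
  X <- matrix(stats::runif(200), 50, 4)
  y <- X[, 1] + stats::rnorm(50, 0, 0.1)
  a <- fit_tree(X, y, max_depth = 3, split_mode = "random-threshold",
                rng_seed = 7)
  b <- fit_tree(X, y, max_depth = 3, split_mode = "random-threshold",
                rng_seed = 7)
  expect_identical(a, b)
})

test_that("cover is conserved at every internal node of fitted trees", {
  d <- small_planted_data()
  ens <- fit_ensemble(d$X[1:100, ], d$y[1:100], kind = "bagged", n_trees = 5,
                      max_depth = 6, mtry = "sqrt", rng_seed = 3)
  for (tr in ens$trees) expect_silent(shapfp:::validate_tree(tr))
})

test_that("boosted ensembles start at the mean and reduce training error", {
  d <- small_planted_data(n = 150, seed = 5)
  ens0 <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 0)
  expect_equal(predict(ens0, d$X[1, ]), mean(d$y))
  # noiseless additive data: stage-wise training MSE non-increasing
  spec <- synthetic_spec(150, n_bits = 32, bit_density = 0.2,
                         planted = data.frame(bit = c(2, 9, 20),
                                              beta = c(2, 1, 1.5)),
                         noise_sd = 0, rng_seed = 8)
  dn <- gen_potency(spec)
  ens <- fit_ensemble(dn$X, dn$y, kind = "boosted", n_trees = 200,
                      max_depth = 1, learning_rate = 0.1, rng_seed = 8)
  pred <- rep(ens$base_offset, nrow(dn$X))
  mses <- numeric(length(ens$trees))
  for (t in seq_along(ens$trees)) {
    pred <- pred + ens$weights[t] *
      shapfp:::predict_tree_matrix(ens$trees[[t]], dn$X)
    mses[t] <- mean((dn$y - pred)^2)
  }
  expect_true(all(diff(mses) <= 1e-10))
})

test_that("a 1-tree bagged ensemble without bootstrap equals fit_tree", {
  d <- small_planted_data(n = 80, seed = 12)
  ens <- fit_ensemble(d$X, d$y, kind = "bagged", n_trees = 1,
                      bootstrap = FALSE, max_depth = 4, rng_seed = 2)
  tr <- fit_tree(d$X, d$y, max_depth = 4)
  expect_equal(predict(ens, d$X), shapfp:::predict_tree_matrix(tr, d$X))
})

test_that("extremely randomized ensembles are seeded and use the full set", {
  d <- small_planted_data(n = 80, seed = 13)
  a <- fit_ensemble(d$X, d$y, kind = "extra", n_trees = 5, max_depth = 4,
                    rng_seed = 4)
  b <- fit_ensemble(d$X, d$y, kind = "extra", n_trees = 5, max_depth = 4,
                    rng_seed = 4)
  expect_identical(a, b)
  expect_equal(a$trees[[1]]$cover[1], nrow(d$X))  # no bootstrap
})

test_that("negative tree counts are rejected", {
  d <- small_planted_data(n = 50, seed = 14)
  expect_error(fit_ensemble(d$X, d$y, n_trees = -1), "n_trees")
})

test_that("random fixture trees have the right shape and are seeded", {
  t0 <- random_tree(5, 0, rng_seed = 1)
  expect_length(t0$feature, 1L)
  t3 <- random_tree(10, 3, rng_seed = 2)
  expect_identical(sum(is.na(t3$feature)), 8L)     # leaves
  expect_identical(sum(!is.na(t3$feature)), 7L)    # internal
  expect_identical(random_tree(10, 3, rng_seed = 2), t3)
  expect_false(identical(random_tree(10, 3, rng_seed = 3), t3))
})

test_that("JSON round trip preserves every ensemble field", {
  trees <- lapply(1:3, function(s) random_tree(6, 3, rng_seed = s))
  ens <- tree_ensemble(trees, weights = c(0.2, 0.3, 0.5), base_offset = 1.25)
  js <- ensemble_to_json(ens)
  back <- ensemble_from_json(js)
  expect_equal(back, ens)
  expect_identical(as.character(ensemble_to_json(back)), as.character(js))
  # file round trip
  path <- tempfile(fileext = ".json")
  ensemble_to_json(ens, path)
  expect_equal(ensemble_from_json(path), ens)
})

test_that("malformed covers are rejected as model-format errors", {
  bad <- make_stump()
  bad$cover[2] <- 99
  expect_error(tree_ensemble(list(bad)), "cover conservation")
})

test_that("xgboost boosters map onto the schema with matching predictions", {
  library(xgboost)
  set.seed(31)
  X <- matrix(stats::runif(150 * 6), 150, 6)
  y <- 2 * X[, 1] - X[, 4] + stats::rnorm(150, 0, 0.05)
  bst <- xgboost(x = X, y = y, nrounds = 8, max_depth = 3, verbosity = 0,
                 nthread = 1)
  ens <- as_tree_ensemble_xgb(bst, 6)
  Xt <- matrix(stats::runif(40 * 6), 40, 6)
  expect_equal(predict(ens, Xt), as.numeric(predict(bst, Xt)),
               tolerance = 1e-5)
})
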