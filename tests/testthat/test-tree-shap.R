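# Tree SHAP: oracle equivalence, axioms, linearity, determinism.

test_that("the 50/50 stump gets base 15 and phi +5", {
  ens <- tree_ensemble(list(make_stump()))
  e <- explain_tree(ens, 1)
  expect_equal(e$base_value, 15)
  expect_equal(unname(e$phi), 5)
  expect_equal(e$fx, 20)
  e0 <- explain_tree(ens, 0)
  expect_equal(unname(e0$phi), -5)
})

test_that("features never used in any tree get exactly zero", {
  tr <- random_tree(3, 3, rng_seed = 5)
  ens <- tree_ensemble(list(tr))
  x <- c(stats::runif(3), 0.5, 0.5)   # features 4 and 5 unused
  e <- explain_tree(ens, x)
  expect_identical(unname(e$phi[4:5]), c(0, 0))
})

test_that("tree SHAP equals brute-force enumeration on random fixtures", {
  maxdev <- 0
  for (s in 1:25) {
    tr <- random_tree(9, 4, rng_seed = 200 + s)
    ens <- tree_ensemble(list(tr))
    set.seed(s)
    x <- stats::runif(9)
    a <- explain_tree(ens, x)
    b <- exact_shapley(tree_value_fn(ens, x))
    maxdev <- max(maxdev, max(abs(a$phi - b$phi)),
                  abs(a$base_value - b$base_value))
  }
  expect_lt(maxdev, 1e-8)
})

test_that("duplicated split features along a path are handled", {
  # depth-3 tree reusing feature 1 on the same path
  tr <- shapfp:::new_tree(
    feature   = c(1, 2, 1, NA, NA, NA, NA),
    threshold = c(0.5, 0.3, 0.2, NA, NA, NA, NA),
    left      = c(2, 4, 6, NA, NA, NA, NA),
    right     = c(3, 5, 7, NA, NA, NA, NA),
    cover     = c(100, 60, 40, 20, 40, 15, 25),
    value     = c(0, 0, 0, 1, 2, 3, 4))
  ens <- tree_ensemble(list(tr))
  for (x in list(c(0.1, 0.1), c(0.4, 0.9), c(0.9, 0.2))) {
    a <- explain_tree(ens, x)
    b <- exact_shapley(tree_value_fn(ens, x))
    expect_lt(max(abs(a$phi - b$phi)), 1e-10)
  }
})

test_that("ensemble explanations are the weighted sum of per-tree ones", {
  trees <- lapply(1:4, function(k) random_tree(6, 3, rng_seed = 300 + k))
  w <- c(0.1, 0.4, 0.2, 0.3)
  ens <- tree_ensemble(trees, weights = w, base_offset = 2)
  set.seed(1)
  x <- stats::runif(6)
  whole <- explain_tree(ens, x)
  parts <- lapply(trees, function(tr) {
    explain_tree(tree_ensemble(list(tr)), x)
  })
  combined <- Reduce(`+`, Map(function(e, wi) wi * e$phi, parts, w))
  expect_lt(max(abs(whole$phi - combined)), 1e-10)
  base_combined <- 2 + sum(w * vapply(parts, `[[`, numeric(1), "base_value"))
  expect_equal(whole$base_value, base_combined, tolerance = 1e-10)
})

test_that("batch explanation preserves order, determinism and additivity", {
  d <- small_planted_data(n = 100, n_bits = 32, seed = 33)
  ens <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 25, max_depth = 3,
                      rng_seed = 33)
  X3 <- d$X[c(1, 1, 2), ]
  E <- explain_tree_batch(ens, X3)
  expect_length(E, 3L)
  expect_identical(E[[1]], E[[2]])            # duplicated row, bit-identical
  expect_identical(E[[1]], explain_tree(ens, d$X[1, ]))
  gaps <- vapply(explain_tree_batch(ens, d$X),
                 function(e) abs(local_accuracy_gap(e)), numeric(1))
  expect_lt(max(gaps), 1e-9)
  expect_error(explain_tree_batch(ens, d$X[1, ]), "matrix")
})

test_that("repeated runs are bit-identical (no stochastic component)", {
  ens <- tree_ensemble(lapply(1:3, function(k) random_tree(7, 3,
                                                           rng_seed = 400 + k)),
                       weights = 1 / 3)
  x <- stats::runif(7)
  expect_identical(explain_tree(ens, x), explain_tree(ens, x))
  expect_null(explain_tree(ens, x)$seed)
})

test_that("runtime stays polynomial when depth doubles", {
  x <- stats::runif(12)
  ens4 <- tree_ensemble(list(random_tree(12, 4, rng_seed = 1)))
  ens8 <- tree_ensemble(list(random_tree(12, 8, rng_seed = 1)))
  t4 <- system.time(for (i in 1:5) explain_tree(ens4, x))[3]
  t8 <- system.time(for (i in 1:5) explain_tree(ens8, x))[3]
  # leaves grow 16x; an exponential-in-coalitions method would blow up by
  # 2^(2^8)/2^(2^4) -- allow generous polynomial headroom only
  expect_lt(t8, max(0.5, 500 * max(t4, 1e-3)))
})

test_that("cover violations surface as model-format errors", {
  bad <- make_stump()
  bad$cover[3] <- 0; bad$cover[2] <- 0
  ens <- structure(list(trees = list(bad), weights = 1, base_offset = 0,
                        task = "regression"), class = "TreeEnsemble")
  expect_error(explain_tree(ens, 1), "cover")
})

test_that("tree SHAP agrees with xgboost's contribution output", {
  library(xgboost)
  set.seed(41)
  X <- matrix(stats::runif(200 * 8), 200, 8)
  y <- 2 * X[, 1] - X[, 3] + X[, 5] * X[, 6] + stats::rnorm(200, 0, 0.05)
  bst <- xgboost(x = X, y = y, nrounds = 12, max_depth = 3, verbosity = 0,
                 nthread = 1)
  ens <- as_tree_ensemble_xgb(bst, 8)
  Xt <- matrix(stats::runif(10 * 8), 10, 8)
  contrib <- predict(bst, Xt, type = "contrib")
  for (i in 1:10) {
    e <- explain_tree(ens, Xt[i, ])
    expect_equal(unname(e$phi), unname(contrib[i, 1:8]), tolerance = 1e-5)
    expect_equal(e$base_value, unname(contrib[i, 9]), tolerance = 1e-5)
  }
})
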