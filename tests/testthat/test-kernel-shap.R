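# Kernel SHAP: kernel weights, coalition sampling, constrained regression.

test_that("the Shapley kernel weight matches its closed form", {
  expect_equal(shapley_kernel_weight(4, 1), 0.25)
  expect_equal(shapley_kernel_weight(2, 1), 0.5)
  expect_identical(shapley_kernel_weight(5, 0), Inf)
  expect_identical(shapley_kernel_weight(5, 5), Inf)
  expect_equal(shapley_kernel_weight(6, 3), 5 / (choose(6, 3) * 9))
  expect_error(shapley_kernel_weight(4, 5), "size")
})

test_that("coalition sampling enumerates when affordable and is seeded", {
  cs <- sample_coalitions(3, kernel_config(n_samples = 64))
  expect_identical(nrow(cs$Z), 6L)             # 2^3 - 2 interior masks
  expect_true(cs$complete)
  expect_false(any(rowSums(cs$Z) %in% c(0, 3)))
  a <- sample_coalitions(12, kernel_config(n_samples = 300, rng_seed = 5))
  b <- sample_coalitions(12, kernel_config(n_samples = 300, rng_seed = 5))
  expect_identical(a, b)
  d <- sample_coalitions(12, kernel_config(n_samples = 300, rng_seed = 6))
  expect_false(identical(a$Z, d$Z))
})

test_that("sampled coalition sizes are symmetric about M/2", {
  cs <- sample_coalitions(10, kernel_config(n_samples = 512, rng_seed = 2))
  tab <- table(cs$size)
  sizes <- as.integer(names(tab))
  for (s in sizes[sizes < 5]) {
    if ((10 - s) %in% sizes) {
      expect_equal(unname(tab[as.character(s)]),
                   unname(tab[as.character(10 - s)]), tolerance = 0.3)
    }
  }
})

test_that("linear models at full enumeration recover w * (x - reference)", {
  w <- c(1, -2, 0.5, 3, 0)
  pf <- linear_predictor(w, 1)
  x <- c(1, 0, 1, 1, 0)
  ref <- c(0, 1, 0, 0, 0)
  e <- explain_kernel(pf, x, ref, kernel_config(n_samples = 64, rng_seed = 1))
  expect_equal(unname(e$phi), w * (x - ref), tolerance = 1e-10)
  expect_equal(e$base_value, pf(matrix(ref, 1)))
})

test_that("local accuracy is exact by construction", {
  d <- small_planted_data(n = 120, n_bits = 24, seed = 21)
  ens <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 30, max_depth = 2,
                      rng_seed = 21)
  pf <- function(X) predict(ens, X)
  ref <- prevalent_reference(d$X)
  for (i in c(1, 7)) {
    e <- explain_kernel(pf, d$X[i, ], ref,
                        kernel_config(n_samples = 100, rng_seed = i))
    expect_lt(abs(local_accuracy_gap(e)), 1e-6)
    expect_equal(e$fx, predict(ens, d$X[i, ]))
  }
})

test_that("full-enumeration kernel SHAP equals the exact oracle", {
  set.seed(77)
  trees <- lapply(1:5, function(k) random_tree(8, 3, rng_seed = 70 + k))
  ens <- tree_ensemble(trees, weights = 1 / 5)
  pf <- function(X) predict(ens, X)
  x <- round(stats::runif(8))
  ref <- 1 - x
  ek <- explain_kernel(pf, x, ref, kernel_config(n_samples = 2^8))
  eo <- exact_shapley(interventional_value_fn(pf, x, ref, "prevalent"))
  expect_lt(max(abs(ek$phi - eo$phi)), 1e-6)
  expect_equal(ek$base_value, eo$base_value, tolerance = 1e-10)
})

test_that("features equal to the reference get zero and stay out", {
  w <- c(2, 1, -1, 4)
  pf <- linear_predictor(w)
  x <- c(1, 0, 1, 0)
  ref <- c(1, 0, 0, 1)   # features 1 and 2 match the reference
  e <- explain_kernel(pf, x, ref, kernel_config(n_samples = 16))
  expect_identical(unname(e$phi[1:2]), c(0, 0))
  expect_equal(unname(e$phi[3:4]), w[3:4] * (x[3:4] - ref[3:4]),
               tolerance = 1e-10)
})

test_that("degenerate universes are handled", {
  pf <- linear_predictor(c(1, 1))
  # nothing varies
  e0 <- explain_kernel(pf, c(1, 0), c(1, 0), kernel_config())
  expect_identical(unname(e0$phi), c(0, 0))
  # one varying feature takes the whole difference
  e1 <- explain_kernel(pf, c(1, 1), c(1, 0), kernel_config())
  expect_equal(unname(e1$phi), c(0, 1))
  # too few samples for the varying features
  expect_error(explain_kernel(linear_predictor(rep(1, 30)), rep(1, 30),
                              rep(0, 30), kernel_config(n_samples = 8)),
               "n_samples")
})

test_that("seed variability vanishes at full enumeration and shrinks with n", {
  set.seed(3)
  trees <- lapply(1:5, function(k) random_tree(10, 3, rng_seed = 90 + k))
  ens <- tree_ensemble(trees, weights = 1 / 5)
  pf <- function(X) predict(ens, X)
  x <- round(stats::runif(10)); ref <- 1 - x
  oracle <- exact_shapley(interventional_value_fn(pf, x, ref, "prevalent"))
  full <- seed_variability(function(s) {
    explain_kernel(pf, x, ref, kernel_config(n_samples = 2^10, rng_seed = s))
  }, seeds = 1:3, oracle = oracle)
  expect_equal(full$max_sd, 0)
  expect_lt(full$mad_mean, 1e-10)
  small <- seed_variability(function(s) {
    explain_kernel(pf, x, ref, kernel_config(n_samples = 40, rng_seed = s))
  }, seeds = 1:5, oracle = oracle)
  big <- seed_variability(function(s) {
    explain_kernel(pf, x, ref, kernel_config(n_samples = 320, rng_seed = s))
  }, seeds = 1:5, oracle = oracle)
  expect_gt(small$max_sd, big$max_sd)
  expect_gt(small$mad_mean, big$mad_mean)
})

test_that("non-scalar predictors violate the contract loudly", {
  bad <- function(X) cbind(X[, 1], X[, 2])
  expect_error(explain_kernel(bad, c(1, 1), c(0, 0), kernel_config()),
               "one numeric value per row")
})
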