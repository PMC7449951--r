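# Metrics, agreement reports, rankings, perturbation experiments.

test_that("classification metrics match hand computation", {
  # perfect prediction
  lab <- c(rep(1, 50), rep(0, 50))
  sc <- c(rep(0.9, 50), rep(0.1, 50))
  m <- classification_metrics(lab, sc)
  expect_equal(unname(m$values["MCC"]), 1)
  expect_equal(unname(m$values["BA"]), 1)
  expect_equal(unname(m$values["AUC"]), 1)
  # TP=40 FN=10 TN=35 FP=15: BA = (0.8 + 0.7) / 2, MCC = 1250/sqrt(...)
  lab2 <- c(rep(1, 50), rep(0, 50))
  sc2 <- c(rep(1, 40), rep(0, 10), rep(1, 15), rep(0, 35))
  m2 <- classification_metrics(lab2, sc2)
  expect_identical(unname(m2$counts), c(40L, 35L, 15L, 10L))
  expect_equal(unname(m2$values["BA"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(m2$values["MCC"]),
               1250 / sqrt(55 * 50 * 50 * 45), tolerance = 1e-12)
  expect_warning(classification_metrics(rep(1, 5), stats::runif(5)),
                 "single-class")
})

test_that("AUC equals the Mann-Whitney rank statistic with ties", {
  lab <- c(1, 1, 0, 0, 1)
  sc <- c(0.9, 0.7, 0.7, 0.2, 0.4)
  m <- classification_metrics(lab, sc)
  # pairwise: P(score_pos > score_neg) + 0.5 P(tie), 6 pairs
  pos <- sc[lab == 1]; neg <- sc[lab == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(unname(m$values["AUC"]), mean(pairs), tolerance = 1e-12)
})

test_that("regression metrics match hand computation", {
  m <- regression_metrics(c(1, 2, 3), c(1, 3, 5))
  expect_equal(unname(m$values["MAE"]), 1, tolerance = 1e-12)
  expect_equal(unname(m$values["MSE"]), 5 / 3, tolerance = 1e-12)
  expect_equal(unname(m$values["R2"]), -1.5, tolerance = 1e-12)
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(perfect$values), c(0, 0, 1))
  null_model <- regression_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(unname(null_model$values["R2"]), 0)
  expect_warning(regression_metrics(rep(2, 4), c(1, 2, 3, 4)), "constant")
})

test_that("agreement of a set with itself and with its negation is total", {
  d <- small_planted_data(n = 60, n_bits = 16, seed = 51)
  ens <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 15, max_depth = 2,
                      rng_seed = 51)
  A <- explain_tree_batch(ens, d$X[1:10, ])
  rep_same <- compare_attributions(A, A, k_grid = c(5, 10))
  expect_equal(rep_same$pearson_r_abs, 1)
  expect_equal(unname(rep_same$topk_overlap), c(5, 10))
  B <- lapply(A, function(e) { e$phi <- -e$phi; e })
  expect_equal(compare_attributions(A, B, k_grid = 5)$pearson_r_abs, 1)
  expect_error(compare_attributions(A, A[1:3]), "equal length")
})

test_that("top-k overlap counts the ranking intersection", {
  mk <- function(order_idx) {
    phi <- numeric(10)
    phi[order_idx] <- seq(10, 10 - length(order_idx) + 1)
    new_explanation(0, phi, 1:10, sum(phi), "tree")
  }
  A <- list(mk(c(1, 2, 3, 4, 5)))
  B <- list(mk(c(1, 3, 9, 2, 8)))
  rep <- compare_attributions(A, B, k_grid = 5)
  expect_equal(unname(rep$topk_overlap), 3)
})

test_that("global ranking orders by mean |phi| with index tie-breaks", {
  e1 <- new_explanation(0, c(0.5, 2, -3, 0), 1:4, -0.5, "tree")
  expect_identical(global_ranking(list(e1)), c(3L, 2L, 1L, 4L))
  # tie between features 1 and 2 -> lower index first
  e2 <- new_explanation(0, c(1, -1, 0.2, 0), 1:4, 0.2, "tree")
  expect_identical(global_ranking(list(e2))[1:2], c(1L, 2L))
  # permuting compounds leaves the ranking unchanged
  d <- small_planted_data(n = 50, n_bits = 16, seed = 52)
  ens <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 10, max_depth = 2,
                      rng_seed = 52)
  E <- explain_tree_batch(ens, d$X[1:20, ])
  expect_identical(global_ranking(E), global_ranking(rev(E)))
})

test_that("planted bits dominate the global ranking on strong synthetics", {
  spec <- synthetic_spec(500, n_bits = 128, bit_density = 0.1,
                         n_planted = 10, beta_range = c(1, 2),
                         noise_sd = 0.2, rng_seed = 53)
  d <- gen_potency(spec)
  ens <- fit_ensemble(d$X, d$y, kind = "boosted", n_trees = 80, max_depth = 3,
                      rng_seed = 53)
  rk <- global_ranking(explain_tree_batch(ens, d$X[1:50, ]))
  expect_gte(planted_recovery(rk, d$truth, 10), 8)
})

test_that("perturbation trajectories start unperturbed and exhaust correctly", {
  w <- c(2, 1, 3, 0.5, 0, 0)
  pf <- linear_predictor(w, 5)
  x <- c(1, 1, 1, 1, 0, 0)
  e <- explain_kernel(pf, x, rep(0, 6), kernel_config(n_samples = 64))
  t0 <- perturbation_experiment(pf, x, e, "remove", "shap", n_steps = 0)
  expect_equal(t0$predictions, pf(matrix(x, 1)))
  # removing every present bit reaches the zero-vector prediction
  tall <- perturbation_experiment(pf, x, e, "remove", "shap", n_steps = 4)
  expect_equal(tall$predictions[1], pf(matrix(x, 1)))
  expect_equal(tall$predictions[5], pf(matrix(0, 1, 6)))
  # shap order flips the largest positive contribution first
  expect_identical(tall$steps[1, 1], 3L)
  # additive positive-weight model: shap-guided removal is non-increasing
  expect_true(all(diff(tall$predictions) <= 1e-12))
})

test_that("add mode grows from the zero vector along the compound's bits", {
  w <- c(2, 1, 3, 0.5)
  pf <- linear_predictor(w, 1)
  x <- c(1, 0, 1, 1)
  e <- explain_kernel(pf, x, rep(0, 4), kernel_config(n_samples = 16))
  tr <- perturbation_experiment(pf, x, e, "add", "shap", n_steps = 3)
  expect_equal(tr$predictions[1], 1)           # f(zero vector)
  expect_equal(tr$predictions[4], pf(matrix(x, 1)))
  expect_identical(tr$steps[1, ], c(3L, 1L, 4L))  # descending positive phi
})

test_that("random strategies are seeded trial means over the right pools", {
  w <- rep(1, 8)
  pf <- linear_predictor(w)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  a <- perturbation_experiment(pf, x, NULL, "remove", "random_present",
                               n_steps = 2, n_trials = 50, rng_seed = 4)
  b <- perturbation_experiment(pf, x, NULL, "remove", "random_present",
                               n_steps = 2, n_trials = 50, rng_seed = 4)
  expect_identical(a, b)
  expect_true(all(a$steps %in% 1:4))           # only present bits
  # removing a present bit always lowers this model by exactly 1
  expect_equal(a$predictions, c(4, 3, 2))
  # random_all can hit absent bits, so the mean drop is smaller
  c_all <- perturbation_experiment(pf, x, NULL, "remove", "random_all",
                                   n_steps = 2, n_trials = 400, rng_seed = 4)
  expect_lt(c_all$predictions[1] - c_all$predictions[3],
            a$predictions[1] - a$predictions[3])
  expect_warning(
    perturbation_experiment(pf, x, NULL, "remove", "random_present",
                            n_steps = 10, n_trials = 5, rng_seed = 1),
    "truncat")
})

test_that("agreement reports serialize to TSV", {
  e <- new_explanation(0, c(1, 2, 3), 1:3, 6, "tree")
  rep <- compare_attributions(list(e), list(e), k_grid = c(2, 3))
  path <- tempfile(fileext = ".tsv")
  write_agreement_tsv(rep, path)
  df <- utils::read.delim(path)
  expect_identical(nrow(df), 3L)
  expect_equal(df$value[1], 1)
})
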