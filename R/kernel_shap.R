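# Model-agnostic SHAP: a local linear surrogate g(z') = phi0 + sum phi_i z'_i
# fitted by Shapley-kernel weighted least squares over feature coalitions,
# with local accuracy (phi0 + sum phi = f(x)) imposed as a hard equality
# constraint. At full coalition enumeration the solution equals the exact
# Shapley values of the same value function; under sampling it is a seeded,
# variance-reduced (paired, size-stratified) estimator.

#' Shapley kernel weight
#'
#' `pi_x(z') = (M - 1) / (choose(M, s) * s * (M - s))` for a coalition of
#' size `s` out of `M` features; the boundary coalitions `s = 0, M` carry
#' infinite weight (they are enforced exactly, not regressed).
#'
#' @param M Number of features in play.
#' @param s Coalition size.
#' @return Positive weight, or `Inf` for boundary coalitions.
#' @export
shapley_kernel_weight <- function(M, s) {
  if (any(s < 0 | s > M)) stop_domain("coalition size must lie in [0, M]")
  ifelse(s == 0 | s == M, Inf, (M - 1) / (choose(M, s) * s * (M - s)))
}

#' Kernel SHAP configuration
#'
#' @param n_samples Number of coalition rows for the surrogate regression
#'   (must be at least the number of varying features).
#' @param rng_seed Seed for coalition sampling.
#' @param substitution_mode `"prevalent"` (single majority-value reference)
#'   or `"background-mean"`.
#' @param regularization_weight Ridge penalty on the attribution vector
#'   (default 0: pure weighted least squares).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(n_samples = 2048L, rng_seed = 1L,
                          substitution_mode = c("prevalent", "background-mean"),
                          regularization_weight = 0) {
  substitution_mode <- match.arg(substitution_mode)
  if (regularization_weight < 0) stop_config("regularization_weight must be >= 0")
  if (n_samples < 1) stop_config("n_samples must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed),
                 substitution_mode = substitution_mode,
                 regularization_weight = regularization_weight),
            class = "kernel_config")
}

#' Sample coalition masks with Shapley-kernel weights
#'
#' Enumerates all `2^M - 2` interior coalitions when they fit the sample
#' budget. Otherwise coalition sizes are filled from the outside in (sizes
#' `1` and `M-1` first), fully enumerating each size pair while the budget
#' allows, and the remainder is drawn in complementary pairs with size
#' probabilities proportional to the remaining kernel mass. Deterministic
#' per seed.
#'
#' @param M Number of features.
#' @param config A [kernel_config()].
#' @return A list with logical matrix `Z` (rows = coalitions), numeric
#'   `weight`, integer `size`, and flag `complete` (full enumeration).
#' @export
sample_coalitions <- function(M, config = kernel_config()) {
  stopifnot(M >= 1)
  if (M == 1) {
    return(list(Z = matrix(logical(0), 0, 1), weight = numeric(0),
                size = integer(0), complete = TRUE))
  }
  n_interior <- 2^M - 2
  if (n_interior <= config$n_samples) {
    masks <- 1:(n_interior)   # skip 0 and 2^M - 1
    Z <- matrix(FALSE, n_interior, M)
    for (j in seq_len(M)) Z[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0
    size <- popcount(masks)
    return(list(Z = Z, weight = shapley_kernel_weight(M, size), size = size,
                complete = TRUE))
  }

  set.seed(config$rng_seed)
  budget <- config$n_samples
  kw <- shapley_kernel_weight(M, 1:(M - 1))
  group_mass <- kw * choose(M, 1:(M - 1))   # kernel mass per size
  Zs <- list(); ws <- numeric(0); sz <- integer(0)
  complete_sizes <- logical(M - 1)

  enumerate_size <- function(s) {
    combs <- utils::combn(M, s)
    Zi <- matrix(FALSE, ncol(combs), M)
    for (k in seq_len(ncol(combs))) Zi[k, combs[, k]] <- TRUE
    Zi
  }

  for (s in seq_len(floor(M / 2))) {
    pair <- unique(c(s, M - s))
    cnt <- sum(choose(M, pair))
    if (budget >= cnt) {
      for (p in pair) {
        Zi <- enumerate_size(p)
        Zs[[length(Zs) + 1L]] <- Zi
        ws <- c(ws, rep(shapley_kernel_weight(M, p), nrow(Zi)))
        sz <- c(sz, rep(p, nrow(Zi)))
        complete_sizes[p] <- TRUE
      }
      budget <- budget - cnt
    } else break
  }

  open_sizes <- which(!complete_sizes)
  if (budget > 0 && length(open_sizes) > 0) {
    # deterministic proportional allocation of the budget over the remaining
    # complementary size pairs (largest-remainder rounding), then uniform
    # paired draws within each pair; each pair's rows jointly carry exactly
    # that pair's kernel mass. Stratifying the allocation removes the
    # size-selection variance of naive kernel-weighted sampling.
    pairs <- unique(lapply(open_sizes[open_sizes <= M / 2],
                           function(s) unique(c(s, M - s))))
    pair_mass <- vapply(pairs, function(p) sum(group_mass[p]), numeric(1))
    alloc <- budget * pair_mass / sum(pair_mass)
    counts <- floor(alloc)
    short <- budget - sum(counts)
    if (short > 0) {
      top_up <- order(alloc - counts, decreasing = TRUE)[seq_len(short)]
      counts[top_up] <- counts[top_up] + 1L
    }
    for (k in seq_along(pairs)) {
      n_k <- counts[k]
      if (n_k == 0) next
      s <- pairs[[k]][1]
      masks <- matrix(FALSE, 2L * ceiling(n_k / 2), M)
      for (j in seq_len(ceiling(n_k / 2))) {
        on <- sample.int(M, s)
        masks[2 * j - 1, on] <- TRUE
        masks[2 * j, ] <- !masks[2 * j - 1, ]   # paired complement
      }
      masks <- masks[seq_len(n_k), , drop = FALSE]
      Zs[[length(Zs) + 1L]] <- masks
      ws <- c(ws, rep(pair_mass[k] / n_k, n_k))
      sz <- c(sz, as.integer(rowSums(masks)))
    }
  }

  list(Z = do.call(rbind, Zs), weight = ws, size = sz, complete = FALSE)
}

#' Kernel SHAP explanation of a black-box prediction
#'
#' Features whose value equals the reference get attribution 0 and leave the
#' regression; the remaining attributions minimize the Shapley-kernel
#' weighted squared error of the surrogate over the sampled coalitions,
#' subject to the equality constraint `sum(phi) = f(x) - f(reference)`
#' (boundary coalitions absorbed into the constraint, which makes local
#' accuracy exact).
#'
#' @param predict Predictor (matrix in, numeric vector out).
#' @param x Feature vector to explain.
#' @param reference Reference vector or background matrix (interpreted per
#'   `config$substitution_mode`).
#' @param config A [kernel_config()].
#' @param universe Feature indices to attribute over (default all of `x`).
#' @return An `Explanation` with `method = "kernel"` and the seed recorded.
#' @export
explain_kernel <- function(predict, x, reference, config = kernel_config(),
                           universe = seq_along(x)) {
  pf <- as_predict_fn(predict)
  universe <- as.integer(universe)
  fx <- pf(matrix(x, 1))

  # features identical to the reference cannot move the prediction here
  if (config$substitution_mode == "prevalent") {
    ref <- if (is.matrix(reference)) prevalent_reference(reference)
           else as.numeric(reference)
    varying <- universe[x[universe] != ref[universe]]
  } else {
    B <- if (is.matrix(reference)) reference else matrix(reference, nrow = 1)
    varying <- universe[vapply(universe, function(j) any(B[, j] != x[j]),
                               logical(1))]
  }

  phi_full <- numeric(length(universe))
  vf <- interventional_value_fn(pf, x, reference,
                                mode = config$substitution_mode,
                                universe = varying)
  f0 <- if (length(varying) == 0) fx else vf$evaluate(integer(0))
  M <- length(varying)
  if (M == 0) {
    return(new_explanation(f0, phi_full, universe, fx, "kernel",
                           config$rng_seed))
  }
  if (M == 1) {
    phi_full[match(varying, universe)] <- fx - f0
    return(new_explanation(f0, phi_full, universe, fx, "kernel",
                           config$rng_seed))
  }
  if (config$n_samples < M) {
    stop_config("n_samples (", config$n_samples, ") must be at least the ",
                "number of varying features (", M, ")")
  }

  cs <- sample_coalitions(M, config)
  y <- vf_eval_masks(vf, cs$Z) - f0
  Zn <- cs$Z * 1
  W <- cs$weight
  total <- fx - f0

  # KKT system of the equality-constrained (optionally ridge) WLS
  ZtW <- t(Zn * W)
  A <- rbind(cbind(2 * (ZtW %*% Zn +
                          diag(config$regularization_weight, M, M)), 1),
             c(rep(1, M), 0))
  b <- c(2 * (ZtW %*% y), total)
  sol <- tryCatch(solve(A, b), error = function(e) {
    stop_domain("singular coalition design (", nrow(Zn), " rows for ", M,
                " features); increase n_samples. [", conditionMessage(e), "]")
  })
  phi_full[match(varying, universe)] <- sol[seq_len(M)]
  new_explanation(f0, phi_full, universe, fx, "kernel", config$rng_seed)
}
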