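# Brute-force Shapley attribution over a pluggable value function: the
# ground-truth oracle against which both the kernel estimator and the tree
# algorithm are checked.
#
# phi_i = sum over coalitions S not containing i of
#         |S|! (M - |S| - 1)! / M! * [f(S u {i}) - f(S)],
# computed by enumerating all 2^M coalitions once (memoized as a vector
# indexed by bitmask) and accumulating weighted marginal contributions.

#' Construct a value function
#'
#' A value function maps a feature coalition to a scalar model output. The
#' optional vectorized form evaluates many coalitions at once and is used by
#' the enumerating explainers.
#'
#' @param evaluate Function taking an integer vector of 1-based feature
#'   indices (the coalition) and returning a scalar.
#' @param universe Ordered integer vector of 1-based feature indices.
#' @param evaluate_masks Optional function taking a logical matrix (rows =
#'   coalitions, columns aligned with `universe`) and returning one value per
#'   row.
#' @return A `ValueFunction`.
#' @export
value_function <- function(evaluate, universe, evaluate_masks = NULL) {
  structure(list(evaluate = evaluate, universe = as.integer(universe),
                 evaluate_masks = evaluate_masks),
            class = "ValueFunction")
}

# Evaluate a ValueFunction on every row of a logical coalition matrix.
vf_eval_masks <- function(vf, Z) {
  if (!is.null(vf$evaluate_masks)) return(vf$evaluate_masks(Z))
  apply(Z, 1, function(z) vf$evaluate(vf$universe[z]))
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all `2^M` coalitions of the value function's universe, memoizes
#' `f(S)` by coalition bitmask, and accumulates the Shapley-weighted marginal
#' contribution of every feature. Exponential in `M`; refuse beyond
#' `max_features` and point at the kernel/tree explainers instead.
#'
#' @param vf A [value_function()].
#' @param max_features Guard on universe size (default 20).
#' @return An `Explanation` with `method = "exact"`.
#' @export
exact_shapley <- function(vf, max_features = 20L) {
  M <- length(vf$universe)
  if (M > max_features) {
    stop_capacity("exact Shapley enumeration over ", M, " features needs 2^", M,
                  " model evaluations; use explain_kernel() (model-agnostic) ",
                  "or explain_tree() (tree ensembles) instead")
  }
  n_masks <- 2^M
  masks <- 0:(n_masks - 1)
  Z <- matrix(FALSE, n_masks, M)
  for (j in seq_len(M)) Z[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0
  f <- vf_eval_masks(vf, Z)
  sizes <- popcount(masks)
  # w[s+1] = s! (M-s-1)! / M!
  w <- exp(lfactorial(0:(M - 1)) + lfactorial(M - 1 - (0:(M - 1))) - lfactorial(M))
  phi <- numeric(M)
  for (j in seq_len(M)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(masks, bit) == 0L)
    phi[j] <- sum(w[sizes[without] + 1] * (f[without + bit] - f[without]))
  }
  new_explanation(base_value = f[1], phi = phi, universe = vf$universe,
                  fx = f[n_masks], method = "exact")
}

#' Interventional value function for a black-box predictor
#'
#' Simulates feature absence by substituting values from a reference:
#' `"prevalent"` mode replaces out-of-coalition features with a single
#' reference vector (by default the feature-wise majority of a background
#' matrix, the prevalent values of the training data); `"background-mean"`
#' mode averages the prediction over substitutions from every background row.
#'
#' @param predict Predictor following the matrix-in / vector-out contract.
#' @param x Feature vector of the instance being explained.
#' @param reference Reference vector, or background matrix.
#' @param mode `"prevalent"` or `"background-mean"`.
#' @param universe Feature indices to attribute over (default: all of `x`).
#' @return A `ValueFunction` whose `evaluate(S)` is the model output when
#'   only coalition features take `x`'s values.
#' @export
interventional_value_fn <- function(predict, x,
                                    reference,
                                    mode = c("prevalent", "background-mean"),
                                    universe = seq_along(x)) {
  mode <- match.arg(mode)
  pf <- as_predict_fn(predict)
  universe <- as.integer(universe)
  if (mode == "prevalent") {
    ref <- if (is.matrix(reference)) prevalent_reference(reference)
           else as.numeric(reference)
    if (length(ref) != length(x)) {
      stop_config("reference length ", length(ref), " does not match x (",
                  length(x), ")")
    }
    eval_masks <- function(Z) {
      Xz <- matrix(rep(ref, each = nrow(Z)), nrow(Z), length(ref))
      for (j in seq_len(ncol(Z))) Xz[Z[, j], universe[j]] <- x[universe[j]]
      pf(Xz)
    }
    evaluate <- function(S) {
      z <- ref
      z[intersect(S, universe)] <- x[intersect(S, universe)]
      pf(matrix(z, 1))
    }
    return(value_function(evaluate, universe, eval_masks))
  }
  B <- if (is.matrix(reference)) reference else matrix(reference, nrow = 1)
  if (nrow(B) == 0) stop_config("background matrix is empty")
  if (ncol(B) != length(x)) stop_config("background width does not match x")
  evaluate <- function(S) {
    Xz <- B
    keep <- intersect(S, universe)
    Xz[, keep] <- matrix(rep(x[keep], each = nrow(B)), nrow(B))
    mean(pf(Xz))
  }
  eval_masks <- function(Z) {
    vals <- numeric(nrow(Z))
    chunk <- max(1L, floor(20000 / nrow(B)))
    k <- 1L
    while (k <= nrow(Z)) {
      rows <- k:min(nrow(Z), k + chunk - 1L)
      big <- B[rep(seq_len(nrow(B)), length(rows)), , drop = FALSE]
      for (ri in seq_along(rows)) {
        sel <- (ri - 1L) * nrow(B) + seq_len(nrow(B))
        on <- universe[Z[rows[ri], ]]
        big[sel, on] <- matrix(rep(x[on], each = nrow(B)), nrow(B))
      }
      v <- pf(big)
      vals[rows] <- colMeans(matrix(v, nrow(B)))
      k <- k + chunk
    }
    vals
  }
  value_function(evaluate, universe, eval_masks)
}

#' Feature-wise majority reference of a background matrix
#'
#' The most frequent value of each column ("prevalent" training values); ties
#' resolve to the smaller value, so all-binary backgrounds give the majority
#' bit with ties at 0.
#'
#' @param X Background matrix.
#' @return Numeric reference vector.
#' @export
prevalent_reference <- function(X) {
  apply(X, 2, function(col) {
    tb <- table(col)
    as.numeric(names(tb)[which.max(tb)])
  })
}

#' Value function of a tree ensemble at an instance
#'
#' `f(S) = base_offset + sum_t weights[t] * E[tree_t | features in S take
#' x's values]`, with the unconditioned branches averaged by training cover.
#' This is the quantity the tree SHAP algorithm attributes exactly.
#'
#' @param ensemble A `TreeEnsemble`.
#' @param x Feature vector.
#' @param universe Feature indices to attribute over (default all of `x`).
#' @return A `ValueFunction`.
#' @export
tree_value_fn <- function(ensemble, x, universe = seq_along(x)) {
  stopifnot(inherits(ensemble, "TreeEnsemble"))
  universe <- as.integer(universe)
  evaluate <- function(S) {
    out <- ensemble$base_offset
    for (t in seq_along(ensemble$trees)) {
      out <- out + ensemble$weights[t] *
        conditional_expectation(ensemble$trees[[t]], x, S)
    }
    out
  }
  eval_masks <- function(Z) {
    # expand coalition columns to full feature width
    Zfull <- matrix(FALSE, nrow(Z), length(x))
    Zfull[, universe] <- Z
    out <- rep(ensemble$base_offset, nrow(Z))
    for (t in seq_along(ensemble$trees)) {
      out <- out + ensemble$weights[t] *
        tree_mask_values(ensemble$trees[[t]], x, Zfull)
    }
    out
  }
  value_function(evaluate, universe, eval_masks)
}
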