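# Exact polynomial-time Shapley attribution for decision-tree ensembles.
#
# The algorithm walks each tree once, maintaining per root-to-leaf path a
# summary of all feature subsets that could reach the current node: for every
# feature on the path, the fraction of subsets flowing down when the feature
# is out of the coalition (cover fraction, "zero fraction") and when it is in
# (0 or 1 depending on x, "one fraction"), together with permutation weights
# for each path length. The path summary is EXTENDed at every split and
# UNWOUND at leaves to read off each feature's weighted marginal
# contribution. The result equals brute-force enumeration of the
# cover-conditional value function, in time polynomial in depth and leaves.

# path matrix columns
.PF <- 1L  # feature index
.PZ <- 2L  # zero fraction
.PO <- 3L  # one fraction
.PW <- 4L  # permutation weight

path_extend <- function(m, pz, po, pi) {
  l <- nrow(m)
  m <- rbind(m, c(pi, pz, po, if (l == 0) 1 else 0))
  if (l > 0) {
    for (r in l:1) {
      m[r + 1, .PW] <- m[r + 1, .PW] + po * m[r, .PW] * r / (l + 1)
      m[r, .PW] <- pz * m[r, .PW] * (l + 1 - r) / (l + 1)
    }
  }
  m
}

# total weight obtained by unwinding element at row `ri` (without mutating)
path_unwound_sum <- function(m, ri) {
  D <- nrow(m) - 1L
  z <- m[ri, .PZ]; o <- m[ri, .PO]
  nxt <- m[D + 1, .PW]
  tot <- 0
  if (D >= 1) {
    if (o != 0) {
      for (i in seq(D - 1, 0)) {
        tmp <- nxt * (D + 1) / ((i + 1) * o)
        tot <- tot + tmp
        nxt <- m[i + 1, .PW] - tmp * z * (D - i) / (D + 1)
      }
    } else {
      for (i in seq(D - 1, 0)) {
        tot <- tot + m[i + 1, .PW] * (D + 1) / (z * (D - i))
      }
    }
  }
  tot
}

# remove element at row `ri`, restoring the weights as if it was never added
path_unwind <- function(m, ri) {
  D <- nrow(m) - 1L
  z <- m[ri, .PZ]; o <- m[ri, .PO]
  nxt <- m[D + 1, .PW]
  if (D >= 1) {
    for (i in seq(D - 1, 0)) {
      r <- i + 1
      if (o != 0) {
        tmp <- m[r, .PW]
        m[r, .PW] <- nxt * (D + 1) / ((i + 1) * o)
        nxt <- tmp - m[r, .PW] * z * (D - i) / (D + 1)
      } else {
        m[r, .PW] <- m[r, .PW] * (D + 1) / (z * (D - i))
      }
    }
  }
  if (ri <= D) for (i in ri:D) m[i, 1:3] <- m[i + 1, 1:3]
  m[seq_len(D), , drop = FALSE]
}

# attributions of one tree at x; returns a vector of length n_features
tree_shap_single <- function(tree, x) {
  phi <- numeric(length(x))
  rec <- function(node, m, pz, po, pi) {
    m <- path_extend(m, pz, po, pi)
    if (is_leaf(tree, node)) {
      D <- nrow(m) - 1L
      if (D >= 1) {
        for (ri in 2:(D + 1)) {
          w <- path_unwound_sum(m, ri)
          f <- m[ri, .PF]
          phi[f] <<- phi[f] + w * (m[ri, .PO] - m[ri, .PZ]) * tree$value[node]
        }
      }
      return(invisible(NULL))
    }
    f <- tree$feature[node]
    if (f > length(x)) stop_domain("feature index ", f - 1L,
                                   " beyond input vector")
    goleft <- x[f] <= tree$threshold[node]
    hot <- if (goleft) tree$left[node] else tree$right[node]
    cold <- if (goleft) tree$right[node] else tree$left[node]
    tot <- tree$cover[tree$left[node]] + tree$cover[tree$right[node]]
    if (tot <= 0) stop_model_format("zero total cover at node ", node)
    hot_z <- tree$cover[hot] / tot
    cold_z <- tree$cover[cold] / tot
    iz <- 1; io <- 1
    prev <- if (nrow(m) > 1) which(m[2:nrow(m), .PF] == f) else integer(0)
    if (length(prev) > 0) {
      ri <- prev[1] + 1L
      iz <- m[ri, .PZ]; io <- m[ri, .PO]
      m <- path_unwind(m, ri)
    }
    rec(hot, m, hot_z * iz, io, f)
    rec(cold, m, cold_z * iz, 0, f)
  }
  rec(1L, matrix(numeric(0), 0, 4), 1, 1, 0L)
  phi
}

#' Exact tree SHAP explanation of an ensemble prediction
#'
#' Computes, for every feature, its exact Shapley value under the ensemble's
#' cover-conditional value function ([tree_value_fn()]), in polynomial time.
#' Per-tree attributions combine linearly with the ensemble weights; the base
#' value is `base_offset` plus the weighted cover-mean of every tree, so
#' `base_value + sum(phi)` equals the ensemble prediction exactly. The method
#' is deterministic: repeated calls are bit-identical.
#'
#' @param ensemble A `TreeEnsemble`.
#' @param x Numeric feature vector covering all features used by the trees.
#' @return An `Explanation` with `method = "tree"` (no seed).
#' @export
explain_tree <- function(ensemble, x) {
  stopifnot(inherits(ensemble, "TreeEnsemble"))
  for (tr in ensemble$trees) validate_tree(tr)
  phi <- numeric(length(x))
  base <- ensemble$base_offset
  for (t in seq_along(ensemble$trees)) {
    phi <- phi + ensemble$weights[t] * tree_shap_single(ensemble$trees[[t]], x)
    base <- base + ensemble$weights[t] * tree_mean_value(ensemble$trees[[t]])
  }
  new_explanation(base, phi, seq_along(x), predict(ensemble, x), "tree")
}

#' Tree SHAP explanations for a matrix of instances
#'
#' @param ensemble A `TreeEnsemble`.
#' @param X Feature matrix (rows = instances).
#' @return List of `Explanation`s in row order.
#' @export
explain_tree_batch <- function(ensemble, X) {
  if (is.null(dim(X))) stop_domain("X must be a matrix (rows = instances)")
  lapply(seq_len(nrow(X)), function(i) explain_tree(ensemble, X[i, ]))
}
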