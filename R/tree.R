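# Decision trees: representation, prediction, coalition-conditional
# expectations, and minimal trainers.
#
# A tree is a list of parallel node vectors (root = node 1): `feature`
# (1-based split feature, NA at leaves), `threshold` (x[feature] <= threshold
# goes left), `left`/`right` (child node indices), `cover` (training rows
# reaching the node) and `value` (leaf output; internal nodes cache the
# cover-weighted mean of their leaves).

new_tree <- function(feature, threshold, left, right, cover, value) {
  structure(list(feature = as.integer(feature), threshold = as.numeric(threshold),
                 left = as.integer(left), right = as.integer(right),
                 cover = as.numeric(cover), value = as.numeric(value)),
            class = "shapfp_tree")
}

is_leaf <- function(tree, node) is.na(tree$feature[node])

validate_tree <- function(tree, tol = 1e-6) {
  for (v in seq_along(tree$feature)) {
    if (!is_leaf(tree, v)) {
      l <- tree$left[v]; r <- tree$right[v]
      if (is.na(l) || is.na(r)) stop_model_format("internal node ", v, " lacks children")
      if (abs(tree$cover[v] - tree$cover[l] - tree$cover[r]) >
          tol * max(1, tree$cover[v])) {
        stop_model_format("cover conservation violated at node ", v)
      }
    }
  }
  invisible(tree)
}

#' Predict a single tree for one feature vector
#' @keywords internal
predict_tree <- function(tree, x) {
  v <- 1L
  while (!is_leaf(tree, v)) {
    f <- tree$feature[v]
    if (f > length(x)) stop_domain("feature index ", f - 1L,
                                   " beyond input vector of length ", length(x))
    v <- if (x[f] <= tree$threshold[v]) tree$left[v] else tree$right[v]
  }
  tree$value[v]
}

# Vectorized tree prediction over rows of X.
predict_tree_matrix <- function(tree, X) {
  node <- rep(1L, nrow(X))
  active <- !is.na(tree$feature[node])
  while (any(active)) {
    idx <- which(active)
    f <- tree$feature[node[idx]]
    if (max(f) > ncol(X)) stop_domain("feature index beyond matrix width")
    goleft <- X[cbind(idx, f)] <= tree$threshold[node[idx]]
    node[idx] <- ifelse(goleft, tree$left[node[idx]], tree$right[node[idx]])
    active[idx] <- !is.na(tree$feature[node[idx]])
  }
  tree$value[node]
}

#' Coalition-conditional expectation of a tree
#'
#' Expected tree output when only the features in coalition `S` are known to
#' take `x`'s values: at a node splitting on a feature in `S` the recursion
#' follows `x`'s branch, otherwise it returns the cover-weighted average of
#' both children; leaves return their value. With `S` equal to all features
#' this reproduces the tree prediction; with `S` empty it is the
#' cover-weighted mean of the leaves.
#'
#' @param tree A tree (from [fit_tree()], [random_tree()] or a deserialized
#'   ensemble).
#' @param x Numeric feature vector.
#' @param S Integer vector of 1-based feature indices forming the coalition.
#' @return Scalar expectation.
#' @export
conditional_expectation <- function(tree, x, S) {
  in_S <- rep(FALSE, max(length(x), 1L))
  if (length(S) > 0) {
    S <- as.integer(S)
    if (any(S < 1L)) stop_domain("coalition members must be positive 1-based indices")
    in_S[S] <- TRUE
  }
  rec <- function(v) {
    if (is_leaf(tree, v)) return(tree$value[v])
    f <- tree$feature[v]
    if (f <= length(in_S) && in_S[f]) {
      if (x[f] <= tree$threshold[v]) rec(tree$left[v]) else rec(tree$right[v])
    } else {
      cl <- tree$cover[tree$left[v]]; cr <- tree$cover[tree$right[v]]
      if (cl + cr <= 0) stop_model_format("zero total cover at node ", v)
      (cl * rec(tree$left[v]) + cr * rec(tree$right[v])) / (cl + cr)
    }
  }
  rec(1L)
}

# Root-to-leaf path decomposition for vectorized coalition evaluation.
# Returns, per leaf: value and a step matrix with columns feature, goes
# (1 if x follows the branch towards this leaf), frac (cover fraction of the
# branch towards this leaf).
leaf_paths <- function(tree, x) {
  paths <- list()
  rec <- function(v, steps) {
    if (is_leaf(tree, v)) {
      paths[[length(paths) + 1L]] <<- list(value = tree$value[v], steps = steps)
      return(invisible(NULL))
    }
    f <- tree$feature[v]
    cl <- tree$cover[tree$left[v]]; cr <- tree$cover[tree$right[v]]
    tot <- cl + cr
    if (tot <= 0) stop_model_format("zero total cover at node ", v)
    goleft <- x[f] <= tree$threshold[v]
    rec(tree$left[v],  rbind(steps, c(f, as.numeric(goleft),  cl / tot)))
    rec(tree$right[v], rbind(steps, c(f, as.numeric(!goleft), cr / tot)))
  }
  rec(1L, matrix(numeric(0), 0, 3))
  paths
}

# Evaluate the coalition-conditional expectation of a tree at x for many
# coalitions at once. Z is a logical matrix (rows = coalitions, columns =
# features; TRUE = feature takes x's value). Returns one value per row.
tree_mask_values <- function(tree, x, Z) {
  paths <- leaf_paths(tree, x)
  out <- numeric(nrow(Z))
  for (p in paths) {
    w <- rep(1, nrow(Z))
    st <- p$steps
    for (k in seq_len(nrow(st))) {
      zf <- Z[, st[k, 1]]
      w <- w * ifelse(zf, st[k, 2], st[k, 3])
      if (!any(w > 0)) break
    }
    out <- out + w * p$value
  }
  out
}

# cover-weighted mean of leaf values = E[tree] under no conditioning
tree_mean_value <- function(tree) {
  conditional_expectation(tree, numeric(0), integer(0))
}

#' Fit a single regression/classification tree
#'
#' Greedy top-down induction with sum-of-squares impurity (for binary 0/1
#' labels this is equivalent to Gini, and leaf values are class-1 fractions,
#' i.e. classification scores). Splits send `x[feature] <= threshold` left;
#' exhaustive search breaks ties by lowest feature index, then lowest
#' threshold. `random-threshold` mode draws one uniform threshold per
#' candidate feature (extremely randomized trees).
#'
#' @param X Numeric feature matrix.
#' @param y Numeric response (0/1 for classification scores).
#' @param max_depth Maximum tree depth (0 = single leaf).
#' @param min_leaf Minimum rows per leaf.
#' @param split_mode `"exhaustive"` or `"random-threshold"`.
#' @param mtry Number of candidate features per split (`NULL` = all).
#' @param rng_seed Optional seed (only consulted for stochastic choices).
#' @return A tree object.
#' @export
fit_tree <- function(X, y, max_depth = 16L, min_leaf = 1L,
                     split_mode = c("exhaustive", "random-threshold"),
                     mtry = NULL, rng_seed = NULL) {
  split_mode <- match.arg(split_mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L * min_leaf && max_depth > 0 && nrow(X) < 2L) {
    stop_config("need at least 2*min_leaf rows to fit a tree")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  p <- ncol(X)
  binary_fast <- all(X %in% c(0, 1))

  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0); nodes$threshold <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$cover <- numeric(0); nodes$value <- numeric(0)
  add_node <- function() {
    k <- length(nodes$feature) + 1L
    nodes$feature[k] <- NA_integer_; nodes$threshold[k] <- NA_real_
    nodes$left[k] <- NA_integer_; nodes$right[k] <- NA_integer_
    nodes$cover[k] <- 0; nodes$value[k] <- 0
    k
  }

  best_split_exhaustive <- function(idx, feats) {
    yy <- y[idx]; n <- length(idx)
    sy <- sum(yy)
    best <- NULL
    base_score <- sy^2 / n
    if (binary_fast) {
      Xs <- X[idx, feats, drop = FALSE]
      n1 <- colSums(Xs)
      s1 <- as.numeric(crossprod(Xs, yy))
      n0 <- n - n1; s0 <- sy - s1
      ok <- n1 >= min_leaf & n0 >= min_leaf
      score <- ifelse(ok, s0^2 / pmax(n0, 1) + s1^2 / pmax(n1, 1), -Inf)
      if (!any(ok)) return(NULL)
      j <- which.max(score)          # first maximum = lowest feature index
      if (score[j] <= base_score + 1e-12) return(NULL)
      return(list(feature = feats[j], threshold = 0.5,
                  left = idx[X[idx, feats[j]] <= 0.5],
                  right = idx[X[idx, feats[j]] > 0.5]))
    }
    for (j in feats) {
      xs <- X[idx, j]
      ord <- order(xs, method = "radix")
      xo <- xs[ord]; yo <- yy[ord]
      cs <- cumsum(yo)
      ks <- which(xo[-n] < xo[-1])   # split after position k
      ks <- ks[ks >= min_leaf & (n - ks) >= min_leaf]
      if (length(ks) == 0) next
      score <- cs[ks]^2 / ks + (sy - cs[ks])^2 / (n - ks)
      m <- which.max(score)          # first max = lowest threshold
      if (score[m] > base_score + 1e-12 &&
          (is.null(best) || score[m] > best$score + 1e-12)) {
        thr <- (xo[ks[m]] + xo[ks[m] + 1]) / 2
        best <- list(score = score[m], feature = j, threshold = thr)
      }
    }
    if (is.null(best)) return(NULL)
    go <- X[idx, best$feature] <= best$threshold
    list(feature = best$feature, threshold = best$threshold,
         left = idx[go], right = idx[!go])
  }

  best_split_random <- function(idx, feats) {
    yy <- y[idx]; n <- length(idx); sy <- sum(yy)
    best <- NULL
    for (j in feats) {
      xs <- X[idx, j]
      lo <- min(xs); hi <- max(xs)
      if (hi <= lo) next
      thr <- stats::runif(1, lo, hi)
      go <- xs <= thr
      nl <- sum(go)
      if (nl < min_leaf || (n - nl) < min_leaf) next
      sl <- sum(yy[go])
      score <- sl^2 / nl + (sy - sl)^2 / (n - nl)
      if (is.null(best) || score > best$score) {
        best <- list(score = score, feature = j, threshold = thr,
                     left = idx[go], right = idx[!go])
      }
    }
    if (is.null(best)) return(NULL)
    best[c("feature", "threshold", "left", "right")]
  }

  build <- function(idx, depth) {
    v <- add_node()
    nodes$cover[v] <- length(idx)
    nodes$value[v] <- mean(y[idx])
    if (depth >= max_depth || length(idx) < 2L * min_leaf ||
        stats::var(y[idx]) == 0 || is.na(stats::var(y[idx]))) {
      return(v)
    }
    feats <- seq_len(p)
    if (!is.null(mtry) && mtry < p) feats <- sort(sample.int(p, mtry))
    sp <- if (split_mode == "exhaustive") best_split_exhaustive(idx, feats)
          else best_split_random(idx, feats)
    if (is.null(sp)) return(v)
    nodes$feature[v] <- sp$feature
    nodes$threshold[v] <- sp$threshold
    nodes$left[v] <- build(sp$left, depth + 1L)
    nodes$right[v] <- build(sp$right, depth + 1L)
    v
  }
  build(seq_len(nrow(X)), 0L)
  new_tree(nodes$feature, nodes$threshold, nodes$left, nodes$right,
           nodes$cover, nodes$value)
}

#' Generate a random full binary tree (fixture generator)
#'
#' Draws features, thresholds in (0,1), positive leaf covers and leaf values
#' uniformly; internal covers are the sums of their children, so cover
#' conservation holds by construction. Deterministic per seed.
#'
#' @param n_features Number of available features (thresholds assume inputs
#'   in `[0,1]`).
#' @param depth Tree depth (0 = single leaf).
#' @param leaf_value_range Length-2 numeric range for leaf values.
#' @param rng_seed Integer seed.
#' @return A tree object.
#' @export
random_tree <- function(n_features, depth, leaf_value_range = c(-1, 1),
                        rng_seed = 1L) {
  stopifnot(depth >= 0, n_features >= 1)
  set.seed(rng_seed)
  nodes <- list(feature = integer(0), threshold = numeric(0),
                left = integer(0), right = integer(0),
                cover = numeric(0), value = numeric(0))
  add <- function(feature, threshold, left, right, cover, value) {
    k <- length(nodes$feature) + 1L
    nodes$feature[k] <<- feature; nodes$threshold[k] <<- threshold
    nodes$left[k] <<- left; nodes$right[k] <<- right
    nodes$cover[k] <<- cover; nodes$value[k] <<- value
    k
  }
  build <- function(d) {
    if (d == 0) {
      return(add(NA_integer_, NA_real_, NA_integer_, NA_integer_,
                 stats::runif(1, 1, 10),
                 stats::runif(1, leaf_value_range[1], leaf_value_range[2])))
    }
    f <- sample.int(n_features, 1L)
    thr <- stats::runif(1)
    v <- add(f, thr, NA_integer_, NA_integer_, 0, 0)
    l <- build(d - 1L); r <- build(d - 1L)
    nodes$left[v] <<- l; nodes$right[v] <<- r
    nodes$cover[v] <<- nodes$cover[l] + nodes$cover[r]
    v
  }
  build(depth)
  tr <- new_tree(nodes$feature, nodes$threshold, nodes$left, nodes$right,
                 nodes$cover, nodes$value)
  # internal nodes cache their cover-weighted subtree mean
  for (v in rev(seq_along(tr$feature))) {
    if (!is.na(tr$feature[v])) {
      l <- tr$left[v]; r <- tr$right[v]
      tr$value[v] <- (tr$cover[l] * tr$value[l] + tr$cover[r] * tr$value[r]) /
        tr$cover[v]
    }
  }
  tr
}
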