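# Tree ensembles: aggregation, trainers (bagged / extremely randomized /
# gradient boosted), JSON interchange, and an adapter from xgboost boosters.
#
# Ensemble prediction is base_offset + sum_t weights[t] * tree_t(x); bagged
# and extremely randomized ensembles use weights 1/T and base_offset 0,
# boosting uses base_offset = mean(y) and weights = learning_rate.

#' Construct a tree ensemble
#'
#' @param trees List of tree objects.
#' @param weights Per-tree weights (recycled scalar allowed).
#' @param base_offset Additive offset (boosting initial prediction).
#' @param task `"regression"` or `"classification-score"`.
#' @return A `TreeEnsemble`.
#' @export
tree_ensemble <- function(trees, weights = 1, base_offset = 0,
                          task = c("regression", "classification-score")) {
  task <- match.arg(task)
  weights <- rep_len(as.numeric(weights), length(trees))
  for (tr in trees) validate_tree(tr)
  structure(list(trees = trees, weights = weights,
                 base_offset = as.numeric(base_offset), task = task),
            class = "TreeEnsemble")
}

#' Predict with a tree ensemble
#'
#' @param object A `TreeEnsemble`.
#' @param newdata Numeric feature vector or matrix (rows = instances).
#' @param ... Unused.
#' @return Numeric prediction(s).
#' @export
predict.TreeEnsemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    out <- object$base_offset
    for (t in seq_along(object$trees)) {
      out <- out + object$weights[t] * predict_tree(object$trees[[t]], newdata)
    }
    return(out)
  }
  out <- rep(object$base_offset, nrow(newdata))
  for (t in seq_along(object$trees)) {
    out <- out + object$weights[t] * predict_tree_matrix(object$trees[[t]], newdata)
  }
  out
}

# predictor-contract closure for a fitted ensemble
ensemble_predict_fn <- function(ensemble) {
  force(ensemble)
  function(X) predict(ensemble, X)
}

#' Fit a decision-tree ensemble
#'
#' `"bagged"` draws a bootstrap sample per tree and a random feature subset
#' per split (random forest); `"extra"` uses the full training set with
#' randomized split thresholds (extremely randomized trees); `"boosted"`
#' starts from the response mean and fits each tree to the current residuals
#' by least squares, scaled by `learning_rate` (gradient boosting).
#'
#' @param X Feature matrix.
#' @param y Response (0/1 labels give classification scores).
#' @param kind `"bagged"`, `"extra"` or `"boosted"`.
#' @param n_trees Number of trees (>= 0; 0 yields the constant predictor).
#' @param max_depth Per-tree depth; defaults to 16 (bagged/extra) or 4
#'   (boosted).
#' @param learning_rate Boosting shrinkage.
#' @param subsample Row fraction per boosted tree (without replacement).
#' @param mtry Candidate features per split: `"sqrt"`, `"log2"`, `"all"` or
#'   an integer.
#' @param min_leaf Minimum rows per leaf.
#' @param bootstrap Draw bootstrap rows for bagged ensembles (disable to make
#'   a 1-tree bagged ensemble coincide with [fit_tree()]).
#' @param rng_seed Integer seed; the fit is deterministic given the seed.
#' @return A `TreeEnsemble`.
#' @export
fit_ensemble <- function(X, y, kind = c("bagged", "extra", "boosted"),
                         n_trees = 300L, max_depth = NULL,
                         learning_rate = 0.1, subsample = 1.0,
                         mtry = "all", min_leaf = 1L, bootstrap = TRUE,
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  if (n_trees < 0) stop_config("n_trees must be >= 0, got ", n_trees)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  task <- if (all(y %in% c(0, 1))) "classification-score" else "regression"
  mtry_n <- if (is.numeric(mtry)) as.integer(mtry)
    else switch(mtry, sqrt = max(1L, floor(sqrt(p))),
                log2 = max(1L, floor(log2(p))), all = p,
                stop_config("unknown mtry rule: ", mtry))
  if (is.null(max_depth)) max_depth <- if (kind == "boosted") 4L else 16L
  set.seed(rng_seed)

  if (kind == "boosted") {
    base <- mean(y)
    resid <- y - base
    trees <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      idx <- if (subsample < 1) sort(sample.int(n, max(2L, floor(subsample * n))))
             else seq_len(n)
      tr <- fit_tree(X[idx, , drop = FALSE], resid[idx], max_depth = max_depth,
                     min_leaf = min_leaf, split_mode = "exhaustive",
                     mtry = if (mtry_n < p) mtry_n else NULL)
      resid <- resid - learning_rate * predict_tree_matrix(tr, X)
      trees[[t]] <- tr
    }
    return(tree_ensemble(trees, weights = learning_rate, base_offset = base,
                         task = task))
  }

  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    if (kind == "bagged") {
      idx <- if (bootstrap) sort(sample.int(n, n, replace = TRUE)) else seq_len(n)
      trees[[t]] <- fit_tree(X[idx, , drop = FALSE], y[idx],
                             max_depth = max_depth, min_leaf = min_leaf,
                             split_mode = "exhaustive",
                             mtry = if (mtry_n < p) mtry_n else NULL)
    } else {
      trees[[t]] <- fit_tree(X, y, max_depth = max_depth, min_leaf = min_leaf,
                             split_mode = "random-threshold",
                             mtry = if (mtry_n < p) mtry_n else p)
    }
  }
  w <- if (n_trees > 0) 1 / n_trees else numeric(0)
  tree_ensemble(trees, weights = w, base_offset = 0, task = task)
}

# ---- JSON interchange -----------------------------------------------------
# Schema: {"task":..., "base_offset":..., "weights":[...], "trees":[[node]]}
# node = {"id","feature","threshold","left","right","cover","value"};
# ids and features 0-based, -1 marks leaves (and their child slots).

tree_to_schema <- function(tree) {
  leaf <- is.na(tree$feature)
  data.frame(
    id = seq_along(tree$feature) - 1L,
    feature = ifelse(leaf, -1L, tree$feature - 1L),
    threshold = ifelse(leaf, 0, tree$threshold),
    left = ifelse(leaf, -1L, tree$left - 1L),
    right = ifelse(leaf, -1L, tree$right - 1L),
    cover = tree$cover,
    value = tree$value
  )
}

tree_from_schema <- function(df) {
  df <- df[order(df$id), ]
  leaf <- df$feature < 0
  tr <- new_tree(ifelse(leaf, NA_integer_, df$feature + 1L),
                 ifelse(leaf, NA_real_, df$threshold),
                 ifelse(leaf, NA_integer_, df$left + 1L),
                 ifelse(leaf, NA_integer_, df$right + 1L),
                 df$cover, df$value)
  validate_tree(tr)
}

#' Serialize a tree ensemble to its JSON interchange form
#'
#' @param ensemble A `TreeEnsemble`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
ensemble_to_json <- function(ensemble, path = NULL) {
  obj <- list(task = ensemble$task,
              base_offset = ensemble$base_offset,
              weights = ensemble$weights,
              trees = lapply(ensemble$trees, tree_to_schema))
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a tree ensemble from JSON
#'
#' @param input Path to a JSON file, or a JSON string.
#' @return A `TreeEnsemble`.
#' @export
ensemble_from_json <- function(input) {
  obj <- jsonlite::fromJSON(input, simplifyDataFrame = TRUE)
  trees <- obj$trees
  if (is.data.frame(trees)) trees <- list(trees)
  tree_ensemble(lapply(trees, tree_from_schema),
                weights = if (length(obj$weights)) obj$weights else numeric(0),
                base_offset = obj$base_offset, task = obj$task)
}

#' Convert an xgboost booster to the package's ensemble schema
#'
#' Maps each booster tree's nodes (feature, split, cover, leaf value) onto
#' the interchange representation, with the booster's base score as
#' `base_offset` and unit tree weights. xgboost routes `x < split` left
#' whereas this schema uses `x <= threshold`; the adapter keeps the split
#' points, so predictions agree except exactly at a split value.
#'
#' @param booster An `xgb.Booster` (regression objective).
#' @param n_features Number of model features.
#' @return A `TreeEnsemble`.
#' @export
as_tree_ensemble_xgb <- function(booster, n_features) {
  if (!requireNamespace("xgboost", quietly = TRUE) ||
      !requireNamespace("data.table", quietly = TRUE)) {
    stop_config("the xgboost adapter requires the xgboost and data.table packages")
  }
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  cfg <- xgboost::xgb.config(booster)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  base <- as.numeric(cfg$learner$learner_model_param$base_score)
  gain_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  trees <- lapply(split(dt, dt$Tree), function(td) {
    key <- td$ID
    node_of <- stats::setNames(seq_len(nrow(td)), key)
    leaf <- td$Feature == "Leaf"
    feat_id <- suppressWarnings(as.integer(sub("^f", "", td$Feature)))
    if (any(!leaf & is.na(feat_id))) {
      stop_model_format("booster features must be unnamed (f0, f1, ...) or ",
                        "plain column indices")
    }
    feat <- ifelse(leaf, NA_integer_, feat_id + 1L)
    tr <- new_tree(feature = feat,
                   threshold = ifelse(leaf, NA_real_, as.numeric(td$Split)),
                   left = ifelse(leaf, NA_integer_, node_of[td$Yes]),
                   right = ifelse(leaf, NA_integer_, node_of[td$No]),
                   cover = td$Cover,
                   value = ifelse(leaf, td[[gain_col]], 0))
    # reorder so the root (node "T-0") is first
    root <- node_of[[paste0(td$Tree[1], "-0")]]
    if (root != 1L) {
      perm <- c(root, setdiff(seq_len(nrow(td)), root))
      inv <- order(perm)
      tr <- new_tree(tr$feature[perm], tr$threshold[perm],
                     inv[tr$left[perm]], inv[tr$right[perm]],
                     tr$cover[perm], tr$value[perm])
    }
    for (v in rev(seq_along(tr$feature))) {
      if (!is.na(tr$feature[v])) {
        l <- tr$left[v]; r <- tr$right[v]
        tr$value[v] <- (tr$cover[l] * tr$value[l] + tr$cover[r] * tr$value[r]) /
          (tr$cover[l] + tr$cover[r])
      }
    }
    tr
  })
  tree_ensemble(trees, weights = 1, base_offset = base, task = "regression")
}
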