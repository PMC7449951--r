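# Performance metrics and comparison machinery: agreement between explanation
# methods, global feature rankings, and feature addition/removal experiments
# with random controls.

#' Classification performance metrics
#'
#' Matthews correlation coefficient and balanced accuracy from the confusion
#' matrix at `threshold`, and AUC as the Mann-Whitney rank statistic (tied
#' scores get mean ranks).
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores (higher = more positive).
#' @param threshold Scores >= threshold are called positive (default 0.5).
#' @return A `MetricReport` with `values` (AUC, MCC, BA), `counts`
#'   (TP, TN, FP, FN) and `n`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop_domain("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop_domain("labels must be binary 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels: MCC/BA/AUC undefined")
    auc <- NaN; mcc <- NaN; ba <- NaN
  } else {
    r <- rank(scores)
    auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom == 0) {
      warning("degenerate confusion matrix: MCC undefined")
      NaN
    } else (tp * tn - fp * fn) / denom
    ba <- (tp / (tp + fn) + tn / (tn + fp)) / 2
  }
  structure(list(task = "classification",
                 values = c(AUC = auc, MCC = mcc, BA = ba),
                 counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 n = length(labels)),
            class = "MetricReport")
}

#' Regression performance metrics
#'
#' Mean absolute error, mean squared error, and the coefficient of
#' determination `R^2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed values.
#' @param y_hat Predicted values.
#' @return A `MetricReport` with `values` (MAE, MSE, R2) and `n`.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop_domain("y and y_hat differ in length")
  if (length(y) < 2) stop_domain("need at least 2 observations")
  mae <- mean(abs(y - y_hat))
  mse <- mean((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("constant response: R2 undefined")
    NaN
  } else 1 - sum((y - y_hat)^2) / sst
  structure(list(task = "regression",
                 values = c(MAE = mae, MSE = mse, R2 = r2),
                 n = length(y)),
            class = "MetricReport")
}

#' Global feature ranking from a set of explanations
#'
#' Features ordered by decreasing mean absolute attribution across
#' explanations; ties break to the lower feature index.
#'
#' @param E List of `Explanation`s sharing a feature universe.
#' @param universe Optional universe override (defaults to the first
#'   explanation's).
#' @return Integer vector of 1-based feature indices, most important first.
#' @export
global_ranking <- function(E, universe = NULL) {
  if (length(E) == 0) stop_domain("need at least one explanation")
  if (is.null(universe)) universe <- E[[1]]$universe
  Phi <- do.call(rbind, lapply(E, function(e) abs(e$phi)))
  imp <- colMeans(Phi)
  universe[order(-imp, universe)]
}

#' Agreement between two sets of explanations
#'
#' Pearson (or Spearman) correlation of absolute attributions pooled over all
#' compounds, per-compound correlations, and the overlap of the two global
#' top-k feature rankings for each k in `k_grid`.
#'
#' @param A,B Lists of `Explanation`s, paired by compound, same universe.
#' @param k_grid Ranking depths for the overlap counts.
#' @param method Correlation type (`"pearson"` default, `"spearman"`
#'   available).
#' @param per_compound_ranking Also compute median per-compound top-k overlap
#'   instead of the global ranking overlap.
#' @return An `AgreementReport`: `pearson_r_abs`, `per_compound_r`,
#'   `topk_overlap` (named by k), `k_grid`.
#' @export
compare_attributions <- function(A, B, k_grid = c(5, 10, 20, 30, 40, 50),
                                 method = c("pearson", "spearman"),
                                 per_compound_ranking = FALSE) {
  method <- match.arg(method)
  if (length(A) != length(B) || length(A) == 0) {
    stop_domain("explanation lists must be non-empty and of equal length")
  }
  Pa <- do.call(rbind, lapply(A, function(e) abs(e$phi)))
  Pb <- do.call(rbind, lapply(B, function(e) abs(e$phi)))
  if (!identical(dim(Pa), dim(Pb))) stop_domain("feature universes differ")
  r_all <- stats::cor(as.vector(Pa), as.vector(Pb), method = method)
  per_r <- vapply(seq_len(nrow(Pa)), function(i) {
    if (stats::sd(Pa[i, ]) == 0 || stats::sd(Pb[i, ]) == 0) return(NA_real_)
    stats::cor(Pa[i, ], Pb[i, ], method = method)
  }, numeric(1))
  k_grid <- k_grid[k_grid <= length(A[[1]]$universe)]
  ra <- global_ranking(A); rb <- global_ranking(B)
  overlap <- vapply(k_grid, function(k) {
    if (per_compound_ranking) {
      per <- vapply(seq_along(A), function(i) {
        ia <- order(-abs(A[[i]]$phi), A[[i]]$universe)[seq_len(k)]
        ib <- order(-abs(B[[i]]$phi), B[[i]]$universe)[seq_len(k)]
        length(intersect(A[[i]]$universe[ia], B[[i]]$universe[ib]))
      }, numeric(1))
      stats::median(per)
    } else {
      length(intersect(ra[seq_len(k)], rb[seq_len(k)]))
    }
  }, numeric(1))
  structure(list(pearson_r_abs = r_all, per_compound_r = per_r,
                 topk_overlap = stats::setNames(overlap, k_grid),
                 k_grid = k_grid, method = method),
            class = "AgreementReport")
}

#' Feature addition/removal perturbation experiment
#'
#' Starting from the compound fingerprint (`mode = "remove"`) or the zero
#' vector (`mode = "add"`), features are flipped one at a time -- ordered by
#' descending signed attribution (`strategy = "shap"`), drawn uniformly from
#' all features (`"random_all"`), or drawn only from the compound's set bits
#' (`"random_present"`) -- and the model is re-evaluated after every flip.
#' Random strategies report the mean trajectory over `n_trials` seeded
#' trials.
#'
#' @param predict Predictor (matrix in, vector out).
#' @param x Binary fingerprint vector.
#' @param explanation `Explanation` for `x` (used by the shap strategy).
#' @param mode `"remove"` or `"add"`.
#' @param strategy `"shap"`, `"random_all"` or `"random_present"`.
#' @param n_steps Number of features to flip (default 5).
#' @param n_trials Trials for random strategies (default 500).
#' @param rng_seed Seed for random strategies.
#' @param order_by `"signed"` (most positive attribution first, default) or
#'   `"absolute"`.
#' @return A `PerturbationTrajectory`: `predictions` (length `n_steps + 1`,
#'   starting at the unperturbed output; trial means for random strategies),
#'   `steps` (matrix of flipped features per trial, 1-based), plus metadata.
#' @export
perturbation_experiment <- function(predict, x, explanation = NULL,
                                    mode = c("remove", "add"),
                                    strategy = c("shap", "random_all",
                                                 "random_present"),
                                    n_steps = 5L, n_trials = 500L,
                                    rng_seed = 1L,
                                    order_by = c("signed", "absolute")) {
  mode <- match.arg(mode); strategy <- match.arg(strategy)
  order_by <- match.arg(order_by)
  pf <- as_predict_fn(predict)
  if (!all(x %in% c(0, 1))) stop_domain("x must be a binary fingerprint vector")
  start <- if (mode == "remove") x else numeric(length(x))
  present <- which(x == 1)

  if (strategy == "shap") {
    if (is.null(explanation)) stop_config("shap strategy needs an explanation")
    pool <- present    # both modes operate on the compound's own bits
    keyed <- if (order_by == "signed") explanation$phi[pool] else abs(explanation$phi[pool])
    ord <- pool[order(-keyed, pool)]
    if (n_steps > length(ord)) {
      warning("n_steps exceeds available features; truncating to ", length(ord))
      n_steps <- length(ord)
    }
    steps <- matrix(ord[seq_len(n_steps)], nrow = 1)
    n_trials <- 1L
  } else {
    pool <- if (strategy == "random_all") seq_along(x) else present
    if (n_steps > length(pool)) {
      warning("n_steps exceeds available features; truncating to ", length(pool))
      n_steps <- length(pool)
    }
    set.seed(rng_seed)
    if (n_steps == 0) {
      steps <- matrix(integer(0), n_trials, 0)
    } else {
      steps <- t(vapply(seq_len(n_trials),
                        function(i) pool[sample.int(length(pool), n_steps)],
                        numeric(n_steps)))
      if (n_steps == 1) steps <- matrix(steps, ncol = 1)
    }
  }

  storage.mode(steps) <- "integer"

  # build all perturbed vectors (trials x (steps+1) rows) and predict at once
  target <- if (mode == "remove") 0 else 1
  rows <- matrix(0, nrow(steps) * (n_steps + 1), length(x))
  for (tr in seq_len(nrow(steps))) {
    v <- start
    base_row <- (tr - 1L) * (n_steps + 1L)
    rows[base_row + 1L, ] <- v
    for (k in seq_len(n_steps)) {
      v[steps[tr, k]] <- target
      rows[base_row + 1L + k, ] <- v
    }
  }
  preds <- matrix(pf(rows), nrow = nrow(steps), byrow = TRUE)
  structure(list(strategy = strategy, mode = mode,
                 steps = steps,
                 predictions = colMeans(preds),
                 n_trials = nrow(steps),
                 rng_seed = if (strategy == "shap") NULL else as.integer(rng_seed)),
            class = "PerturbationTrajectory")
}

#' Seed-to-seed variability of a stochastic explainer
#'
#' Re-runs an explainer with distinct seeds and reports the per-feature
#' standard deviation of the attributions and, when an oracle explanation is
#' supplied, the mean and standard deviation of the correlation (on absolute
#' attributions) with the oracle.
#'
#' @param explainer Function `(seed) -> Explanation`.
#' @param seeds Integer seeds (default `1:5`).
#' @param oracle Optional reference `Explanation` (e.g. from
#'   [exact_shapley()] or [explain_tree()]).
#' @return List: `per_feature_sd`, `max_sd`, and (with an oracle) `r`,
#'   `r_mean`, `r_sd`, `mad_mean` (mean absolute deviation from the oracle).
#' @export
seed_variability <- function(explainer, seeds = 1:5, oracle = NULL) {
  ex <- lapply(seeds, explainer)
  Phi <- do.call(rbind, lapply(ex, function(e) e$phi))
  sds <- apply(Phi, 2, stats::sd)
  out <- list(per_feature_sd = sds, max_sd = max(sds), seeds = seeds)
  if (!is.null(oracle)) {
    out$r <- vapply(ex, function(e) {
      stats::cor(abs(e$phi), abs(oracle$phi))
    }, numeric(1))
    out$r_mean <- mean(out$r)
    out$r_sd <- stats::sd(out$r)
    out$mad <- vapply(ex, function(e) mean(abs(e$phi - oracle$phi)), numeric(1))
    out$mad_mean <- mean(out$mad)
  }
  out
}

#' Write an agreement report as TSV
#'
#' @param report An `AgreementReport`.
#' @param path Output TSV (one row per k plus a pooled-correlation row).
#' @export
write_agreement_tsv <- function(report, path) {
  df <- data.frame(statistic = c("pearson_r_abs",
                                 paste0("topk_overlap_", report$k_grid)),
                   value = c(report$pearson_r_abs, unname(report$topk_overlap)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
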