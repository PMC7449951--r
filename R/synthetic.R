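# Synthetic fingerprint data with known ground truth: sparse binary bit
# matrices, a handful of "planted" activity-determining bits with additive
# effects on a pKi-like response, binary active/inactive labels, and sparse
# multi-target label panels. Everything is deterministic per seed, so every
# explainer and ranking can be scored against the planted truth without any
# external data.

#' Specification of a synthetic fingerprint data set
#'
#' Defaults emulate potency-prediction data: a pKi-like response centred at
#' 7.5 with planted additive bit effects, and (for multi-target panels)
#' sparse activity annotations on the order of 1 percent.
#'
#' @param n_compounds Number of rows.
#' @param n_bits Fingerprint length (default 1024).
#' @param bit_density Marginal probability that a bit is set (default 0.1).
#' @param planted Data frame with columns `bit` (1-based index) and `beta`
#'   (additive effect), or `NULL` to draw `n_planted` bits with effects in
#'   `beta_range`.
#' @param n_planted,beta_range Used when `planted` is `NULL` (default 10
#'   bits, effects 0.5..1.5).
#' @param intercept Baseline response (default 7.5, pKi-like).
#' @param noise_sd Gaussian noise level (default 0.3).
#' @param task `"regression"`, `"classification"` or `"multitarget"`.
#' @param n_targets Targets for multitarget panels.
#' @param annotation_density Probability a compound-target label is observed
#'   (default 0.011).
#' @param block_size Correlated-bit block size; 1 = independent bits. Blocks
#'   share a latent bit flipped independently with probability `block_flip`.
#' @param block_flip Flip probability inside correlated blocks.
#' @param rng_seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, n_bits = 1024L, bit_density = 0.1,
                           planted = NULL, n_planted = 10L,
                           beta_range = c(0.5, 1.5), intercept = 7.5,
                           noise_sd = 0.3,
                           task = c("regression", "classification",
                                    "multitarget"),
                           n_targets = 1L, annotation_density = 0.011,
                           block_size = 1L, block_flip = 0.1,
                           rng_seed = 1L) {
  task <- match.arg(task)
  if (bit_density <= 0 || bit_density >= 1) stop_config("bit_density must lie in (0,1)")
  if (annotation_density <= 0 || annotation_density > 1) {
    stop_config("annotation_density must lie in (0,1]")
  }
  if (!is.null(planted)) {
    stopifnot(all(c("bit", "beta") %in% names(planted)))
    if (anyDuplicated(planted$bit) || any(planted$bit < 1) ||
        any(planted$bit > n_bits)) {
      stop_config("planted bits must be distinct 1-based indices <= n_bits")
    }
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_bits = as.integer(n_bits), bit_density = bit_density,
                 planted = planted, n_planted = as.integer(n_planted),
                 beta_range = beta_range, intercept = intercept,
                 noise_sd = noise_sd, task = task,
                 n_targets = as.integer(n_targets),
                 annotation_density = annotation_density,
                 block_size = as.integer(block_size), block_flip = block_flip,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

draw_bits <- function(spec) {
  n <- spec$n_compounds; p <- spec$n_bits
  if (spec$block_size <= 1L) {
    return(matrix(stats::rbinom(n * p, 1, spec$bit_density), n, p))
  }
  n_blocks <- ceiling(p / spec$block_size)
  latent <- matrix(stats::rbinom(n * n_blocks, 1, spec$bit_density), n, n_blocks)
  X <- latent[, rep(seq_len(n_blocks), each = spec$block_size), drop = FALSE]
  X <- X[, seq_len(p), drop = FALSE]
  flips <- matrix(stats::rbinom(n * p, 1, spec$block_flip), n, p)
  abs(X - flips)
}

draw_planted <- function(spec) {
  if (!is.null(spec$planted)) return(spec$planted)
  bits <- sort(sample.int(spec$n_bits, spec$n_planted))
  data.frame(bit = bits,
             beta = stats::runif(spec$n_planted, spec$beta_range[1],
                                 spec$beta_range[2]))
}

#' Generate a potency-like regression data set
#'
#' `y = intercept + sum_j beta_j X[, bit_j] + N(0, noise_sd)`.
#'
#' @param spec A [synthetic_spec()].
#' @return List `X` (binary matrix), `y`, and `truth` (planted bits/effects,
#'   intercept, noise level, seed).
#' @export
gen_potency <- function(spec) {
  set.seed(spec$rng_seed)
  planted <- draw_planted(spec)
  X <- draw_bits(spec)
  y <- spec$intercept +
    as.numeric(X[, planted$bit, drop = FALSE] %*% planted$beta) +
    stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
  list(X = X, y = y,
       truth = list(planted = planted, intercept = spec$intercept,
                    noise_sd = spec$noise_sd, rng_seed = spec$rng_seed))
}

#' Generate a binary activity classification data set
#'
#' Labels are indicators of the latent potency exceeding `threshold`.
#'
#' @param spec A [synthetic_spec()].
#' @param threshold Activity cutoff on the latent response.
#' @return List `X`, `labels` (0/1), `truth` (includes the threshold and the
#'   realized class balance).
#' @export
gen_classification <- function(spec, threshold = NULL) {
  pot <- gen_potency(spec)
  if (is.null(threshold)) threshold <- stats::median(pot$y)
  labels <- as.integer(pot$y >= threshold)
  truth <- pot$truth
  truth$threshold <- threshold
  truth$balance <- mean(labels)
  list(X = pot$X, labels = labels, truth = truth)
}

#' Generate a sparse multi-target label panel
#'
#' Each target gets its own planted bit set (sharing a fraction `overlap`
#' of bits with the first target's set); labels are thresholded latent
#' responses, and only a sparse random subset of compound-target pairs is
#' observed, mimicking panel annotation densities around 1 percent.
#'
#' @param spec A [synthetic_spec()] with `n_targets`.
#' @param overlap Fraction of each target's planted bits shared with target 1
#'   (1 = identical truth everywhere).
#' @return List `X`, `labels` (matrix with `NA` at unobserved pairs), `mask`
#'   (logical observed matrix), `truth` (per-target planted sets).
#' @export
gen_multitarget <- function(spec, overlap = 0) {
  stopifnot(overlap >= 0, overlap <= 1)
  set.seed(spec$rng_seed)
  base_planted <- draw_planted(spec)
  X <- draw_bits(spec)
  n_shared <- round(overlap * nrow(base_planted))
  per_target <- vector("list", spec$n_targets)
  labels <- matrix(NA_integer_, spec$n_compounds, spec$n_targets)
  full <- matrix(0L, spec$n_compounds, spec$n_targets)
  for (t in seq_len(spec$n_targets)) {
    if (t == 1 || overlap == 1) {
      pl <- base_planted
    } else {
      shared <- base_planted[seq_len(n_shared), , drop = FALSE]
      free <- setdiff(seq_len(spec$n_bits), shared$bit)
      extra_n <- nrow(base_planted) - n_shared
      extra <- data.frame(bit = sort(sample(free, extra_n)),
                          beta = stats::runif(extra_n, spec$beta_range[1],
                                              spec$beta_range[2]))
      pl <- rbind(shared, extra)
    }
    per_target[[t]] <- pl
    y <- spec$intercept +
      as.numeric(X[, pl$bit, drop = FALSE] %*% pl$beta) +
      stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
    full[, t] <- as.integer(y >= stats::median(y))
  }
  mask <- matrix(stats::runif(spec$n_compounds * spec$n_targets) <
                   spec$annotation_density,
                 spec$n_compounds, spec$n_targets)
  labels[mask] <- full[mask]
  list(X = X, labels = labels, mask = mask,
       truth = list(per_target = per_target, overlap = overlap,
                    rng_seed = spec$rng_seed))
}

#' Fixed-weight multi-output fixture model
#'
#' A deterministic linear (or logistic) multi-output predictor with known
#' weights, standing in for trained multi-task networks in explanation
#' tests: closed-form attributions are available for the identity link.
#'
#' @param weights Matrix (features x targets) of weights.
#' @param intercepts Per-target intercepts.
#' @param link `"identity"` or `"logistic"`.
#' @return Function mapping a feature matrix to an output matrix.
#' @export
fixture_multioutput_model <- function(weights, intercepts = 0,
                                      link = c("identity", "logistic")) {
  link <- match.arg(link)
  weights <- as.matrix(weights)
  intercepts <- rep_len(intercepts, ncol(weights))
  function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    eta <- sweep(X %*% weights, 2, intercepts, "+")
    if (link == "logistic") 1 / (1 + exp(-eta)) else eta
  }
}

#' Score a feature ranking against the planted truth
#'
#' @param ranking Integer feature ranking (1-based, most important first).
#' @param truth Truth record from a generator.
#' @param k Depth (default: number of planted bits).
#' @return Number of planted bits among the top k.
#' @export
planted_recovery <- function(ranking, truth, k = nrow(truth$planted)) {
  length(intersect(ranking[seq_len(k)], truth$planted$bit))
}

#' Write a synthetic data set in the pipeline's file formats
#'
#' @param data Output of [gen_potency()] or [gen_classification()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths (fingerprint TSV, response CSV,
#'   truth JSON; bit indices 0-based in files).
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- paste0("cpd", seq_len(nrow(data$X)))
  df <- data.frame(id = ids, data$X, check.names = FALSE)
  names(df)[-1] <- paste0("bit", seq_len(ncol(data$X)) - 1L)
  x_path <- file.path(dir, "fingerprints.tsv")
  utils::write.table(df, x_path, sep = "\t", quote = FALSE, row.names = FALSE)
  y_path <- file.path(dir, "response.csv")
  if (!is.null(data$y)) {
    utils::write.csv(data.frame(id = ids, value = data$y), y_path,
                     row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(id = ids, label = data$labels), y_path,
                     row.names = FALSE, quote = FALSE)
  }
  t_path <- file.path(dir, "truth.json")
  truth <- data$truth
  if (!is.null(truth$planted)) truth$planted$bit <- truth$planted$bit - 1L
  if (!is.null(truth$per_target)) {
    truth$per_target <- lapply(truth$per_target, function(p) {
      p$bit <- p$bit - 1L; p
    })
  }
  jsonlite::write_json(truth, t_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(fingerprints = x_path, response = y_path, truth = t_path))
}
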