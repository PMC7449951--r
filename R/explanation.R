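# Explanation objects: a base value (model output with no features known),
# per-feature attributions, and the model output being explained. All three
# explainers (exact, kernel, tree) return this container and satisfy local
# accuracy: base_value + sum(phi) = fx.

#' Construct an explanation
#'
#' @param base_value Model output under the empty coalition.
#' @param phi Numeric attribution vector aligned with `universe`.
#' @param universe Integer vector of 1-based feature (column) indices the
#'   attributions refer to.
#' @param fx Model output being explained.
#' @param method `"exact"`, `"kernel"` or `"tree"`.
#' @param seed Seed used by stochastic explainers, or `NULL`.
#' @return An `Explanation`.
#' @export
new_explanation <- function(base_value, phi, universe, fx, method,
                            seed = NULL) {
  stopifnot(length(phi) == length(universe))
  structure(list(base_value = as.numeric(base_value),
                 phi = stats::setNames(as.numeric(phi),
                                       paste0("f", universe - 1L)),
                 universe = as.integer(universe),
                 fx = as.numeric(fx), method = method,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "Explanation")
}

#' @export
print.Explanation <- function(x, ...) {
  cat(sprintf("<Explanation: %s> base=%.6g fx=%.6g sum(phi)=%.6g (%d features)\n",
              x$method, x$base_value, x$fx, sum(x$phi), length(x$phi)))
  top <- order(abs(x$phi), decreasing = TRUE)[seq_len(min(5, length(x$phi)))]
  for (i in top) cat(sprintf("  %s: %+0.6g\n", names(x$phi)[i], x$phi[i]))
  invisible(x)
}

#' Local-accuracy residual of an explanation
#'
#' @param e An `Explanation`.
#' @return `base_value + sum(phi) - fx` (should be ~0).
#' @export
local_accuracy_gap <- function(e) {
  e$base_value + sum(e$phi) - e$fx
}

#' Write an explanation as JSON
#'
#' Sparse form: zero attributions are omitted; feature keys are 0-based bit
#' indices.
#'
#' @param e An `Explanation`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
explanation_to_json <- function(e, path = NULL) {
  nz <- which(e$phi != 0)
  phi <- as.list(e$phi[nz])
  names(phi) <- as.character(e$universe[nz] - 1L)
  obj <- list(method = e$method, base_value = e$base_value, fx = e$fx,
              phi = phi, seed = e$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an explanation from JSON
#'
#' @param input Path or JSON string.
#' @param n_features Total feature count (zeros restored for omitted
#'   features); defaults to the largest stored index + 1.
#' @return An `Explanation`.
#' @export
explanation_from_json <- function(input, n_features = NULL) {
  obj <- jsonlite::fromJSON(input)
  idx0 <- as.integer(names(obj$phi))
  if (is.null(n_features)) n_features <- if (length(idx0)) max(idx0) + 1L else 0L
  phi <- numeric(n_features)
  phi[idx0 + 1L] <- unlist(obj$phi)
  new_explanation(obj$base_value, phi, seq_len(n_features), obj$fx,
                  obj$method, obj$seed)
}
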