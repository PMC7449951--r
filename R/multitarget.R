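# Per-output explanation of multi-output predictors (multi-target activity
# profiles) and sign/presence partitioning of contributions for error
# analysis.

#' Explain every output of a multi-target predictor
#'
#' Wraps each requested output of a vector-valued predictor as a scalar
#' prediction function and runs kernel SHAP on it with a shared seed, so the
#' same coalition sample underlies every per-target explanation. Each
#' per-target explanation individually satisfies local accuracy against that
#' output.
#'
#' @param multi_predict Function mapping a feature matrix to a prediction
#'   matrix (rows = instances, columns = targets).
#' @param x Feature vector of the compound.
#' @param target_ids Integer column indices of the outputs to explain
#'   (default: all).
#' @param reference Reference vector or background matrix.
#' @param config A [kernel_config()] shared across targets.
#' @param compound_id Identifier carried into the result.
#' @return A `ProfileExplanation`: list with `compound_id`, `per_target`
#'   (named list of `Explanation`s) and `probabilities` (the raw per-target
#'   outputs for `x`).
#' @export
explain_profile <- function(multi_predict, x, target_ids = NULL, reference,
                            config = kernel_config(), compound_id = "compound") {
  probe <- multi_predict(matrix(x, 1))
  if (is.null(dim(probe))) probe <- matrix(probe, 1)
  n_out <- ncol(probe)
  if (is.null(target_ids)) target_ids <- seq_len(n_out)
  if (any(target_ids < 1 | target_ids > n_out)) {
    stop_domain("target id beyond output width ", n_out)
  }
  per_target <- lapply(target_ids, function(t) {
    pt <- function(X) {
      out <- multi_predict(X)
      if (is.null(dim(out))) out <- matrix(out, ncol = n_out)
      out[, t]
    }
    explain_kernel(pt, x, reference, config)
  })
  names(per_target) <- paste0("target", target_ids)
  structure(list(compound_id = compound_id,
                 per_target = per_target,
                 probabilities = stats::setNames(as.numeric(probe[1, target_ids]),
                                                 paste0("target", target_ids))),
            class = "ProfileExplanation")
}

#' Partition attributions by sign and feature presence
#'
#' Splits the nonzero attributions of an explanation of a binary fingerprint
#' into four quadrants: (present, positive), (present, negative), (absent,
#' positive), (absent, negative). Absent-bit entries have no substructure in
#' the compound (their atom environments are missing), which is exactly why
#' their negative contributions matter for error analysis.
#'
#' @param explanation An `Explanation`.
#' @param x Binary feature vector the explanation refers to.
#' @param k Entries per quadrant in the `top_lists` (by absolute
#'   attribution).
#' @return A `ContributionPartition`: `quadrants` (named list of data frames
#'   with `feature` (1-based) and `phi`) and `top_lists` (top-k per
#'   quadrant).
#' @export
partition_contributions <- function(explanation, x, k = 3L) {
  if (!all(x %in% c(0, 1))) stop_domain("x must be binary for presence partitioning")
  u <- explanation$universe
  phi <- explanation$phi
  nz <- which(phi != 0)
  pres <- x[u[nz]] == 1
  pos <- phi[nz] > 0
  quad <- list(
    present_positive = nz[pres & pos],
    present_negative = nz[pres & !pos],
    absent_positive  = nz[!pres & pos],
    absent_negative  = nz[!pres & !pos]
  )
  quadrants <- lapply(quad, function(ii) {
    df <- data.frame(feature = u[ii], phi = unname(phi[ii]))
    df[order(-abs(df$phi), df$feature), , drop = FALSE]
  })
  top_lists <- lapply(quadrants, function(df) utils::head(df, k))
  structure(list(quadrants = quadrants, top_lists = top_lists, k = as.integer(k)),
            class = "ContributionPartition")
}

#' JSON profile report for a multi-target explanation
#'
#' Per target: output probability, base value, and the top positive/negative
#' contributions split by feature presence, with SMARTS substructures when a
#' fingerprint record is supplied (absent bits carry none).
#'
#' @param profile A `ProfileExplanation`.
#' @param x Binary feature vector.
#' @param record Optional `fingerprint_record` for substructure lookup.
#' @param k Entries per quadrant.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
profile_report_json <- function(profile, x, record = NULL, k = 3L,
                                path = NULL) {
  per <- lapply(names(profile$per_target), function(tn) {
    e <- profile$per_target[[tn]]
    part <- partition_contributions(e, x, k)
    quads <- lapply(part$top_lists, function(df) {
      lapply(seq_len(nrow(df)), function(i) {
        bit0 <- df$feature[i] - 1L
        entry <- list(bit = bit0, phi = df$phi[i])
        if (!is.null(record)) {
          m <- map_bits_to_substructures(record, bit0)[[1]]
          entry$smarts <- m$smarts
          entry$present <- m$present
        }
        entry
      })
    })
    list(probability = unname(profile$probabilities[tn]),
         base_value = e$base_value, fx = e$fx, top_features = quads)
  })
  names(per) <- names(profile$per_target)
  obj <- list(compound_id = profile$compound_id, targets = per)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
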