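# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a over a vector of non-negative integers (each consumed as four
# little-endian bytes). Pure double arithmetic keeps the state exact below
# 2^32, so hashes are platform independent.
fnv1a32 <- function(ints) {
  h <- 2166136261
  for (v in ints) {
    for (shift in c(1, 256, 65536, 16777216)) {
      byte <- floor(v / shift) %% 256
      low <- h %% 256
      h <- h - low + bitwXor(as.integer(low), as.integer(byte))
      # h * 16777619 mod 2^32 via 16-bit limbs (keeps products < 2^53)
      lo <- h %% 65536
      hi <- (h - lo) / 65536
      h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
    }
  }
  h
}

# Stable hash of an arbitrary R object (used to stamp run configs into
# artifacts). Serializes deparsed text, so it only sees values, not bytes.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "exact"), collapse = "\n")
  h <- fnv1a32(utf8ToInt(txt))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# number of set bits for each integer in 0..(2^m - 1), m <= 25
popcount <- function(masks) {
  n <- integer(length(masks))
  v <- masks
  while (any(v > 0)) {
    n <- n + v %% 2L
    v <- v %/% 2L
  }
  n
}

stop_domain <- function(...) {
  stop(structure(class = c("shapfp_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("shapfp_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("shapfp_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_capacity <- function(...) {
  stop(structure(class = c("shapfp_capacity_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_model_format <- function(...) {
  stop(structure(class = c("shapfp_model_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Wrap a user-supplied predictor so it always maps a numeric matrix
# (rows = instances) to a numeric vector of length nrow.
as_predict_fn <- function(predict) {
  stopifnot(is.function(predict))
  function(X) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    out <- predict(X)
    if (!is.numeric(out) || length(out) != nrow(X)) {
      stop_domain("predict function must return one numeric value per row; ",
                  "got length ", length(out), " for ", nrow(X), " rows")
    }
    as.numeric(out)
  }
}
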