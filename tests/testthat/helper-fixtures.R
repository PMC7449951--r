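# Shared fixtures: molecules, small trees, and independent Shapley oracles.

# 100 diverse valid SMILES built combinatorially (10 scaffolds x 10
# substituents appended at a ring atom).
fixture_smiles <- function(n = 100) {
  scaffolds <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1cc[nH]c1", "C1CCNCC1",
                 "c1ccsc1", "C1CCOC1", "c1ccc2ccccc2c1", "c1ccc(cc1)", "C1CCCC1")
  subs <- c("C", "O", "N(C)C", "Cl", "C(F)(F)F", "C(=O)O", "C(=O)NC", "C#N",
            "S(=O)(=O)N", "OCC=O")
  all <- as.vector(outer(scaffolds, subs, paste0))
  all[seq_len(min(n, length(all)))]
}

# 50/50 stump: x[f] <= thr -> v_left else v_right
make_stump <- function(f = 1, thr = 0.5, v_left = 10, v_right = 20,
                       c_left = 50, c_right = 50) {
  shapfp:::new_tree(feature = c(f, NA, NA), threshold = c(thr, NA, NA),
                    left = c(2, NA, NA), right = c(3, NA, NA),
                    cover = c(c_left + c_right, c_left, c_right),
                    value = c((c_left * v_left + c_right * v_right) /
                                (c_left + c_right), v_left, v_right))
}

# depth-2 tree: root splits feature 1 at 0.5; each child splits feature 2 at
# 0.5; four leaves with given covers/values.
make_depth2_tree <- function(covers = c(10, 30, 25, 35),
                             values = c(1, 2, 3, 4)) {
  cl <- covers[1] + covers[2]; cr <- covers[3] + covers[4]
  shapfp:::new_tree(
    feature   = c(1, 2, 2, NA, NA, NA, NA),
    threshold = c(0.5, 0.5, 0.5, NA, NA, NA, NA),
    left      = c(2, 4, 6, NA, NA, NA, NA),
    right     = c(3, 5, 7, NA, NA, NA, NA),
    cover     = c(cl + cr, cl, cr, covers),
    value     = c(0, 0, 0, values))
}

# Independent Shapley oracle: average marginal contribution over every
# feature ordering (usable for |universe| <= 6).
shapley_by_permutations <- function(vf) {
  M <- length(vf$universe)
  stopifnot(M <= 6)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_orders <- perms(vf$universe)
  phi <- stats::setNames(numeric(M), as.character(vf$universe))
  for (ord in all_orders) {
    S <- integer(0)
    prev <- vf$evaluate(S)
    for (f in ord) {
      S <- c(S, f)
      cur <- vf$evaluate(S)
      phi[as.character(f)] <- phi[as.character(f)] + (cur - prev)
      prev <- cur
    }
  }
  unname(phi[as.character(vf$universe)]) / length(all_orders)
}

linear_predictor <- function(w, b = 0) {
  force(w); force(b)
  function(X) as.numeric(X %*% w + b)
}

# small deterministic planted-bit data set shared by several tests
small_planted_data <- function(n = 200, n_bits = 64, seed = 99) {
  bits <- unique(pmax(1L, round(seq(0.1, 0.9, length.out = 5) * n_bits)))
  spec <- synthetic_spec(n, n_bits = n_bits, bit_density = 0.15,
                         planted = data.frame(bit = bits,
                                              beta = c(1.5, 1.2, -1.0, 0.8,
                                                       1.1)[seq_along(bits)]),
                         noise_sd = 0.2, rng_seed = seed)
  gen_potency(spec)
}
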