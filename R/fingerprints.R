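# Folded circular fingerprints with bit -> atom-environment provenance.
#
# Layered atom environments (radius 0..r around each heavy atom) are hashed
# to integer identifiers by iterating FNV-1a over each atom's previous-round
# identifier and its sorted (bond order, neighbour identifier) pairs, then
# folded onto a fixed-length bit vector by modulo mapping. Every emitted
# environment is also rendered as a SMARTS pattern so attributed bits can be
# mapped back to substructures; environments covering an atom set already
# emitted (e.g. a radius-2 shell identical to the radius-1 shell of a
# neighbouring centre) are deduplicated.

#' Fold a raw environment identifier onto a bit index
#'
#' @param raw_id Non-negative integer identifier produced by the environment
#'   hash.
#' @param n_bits Length of the folded fingerprint (>= 2).
#' @return Integer bit index in `[0, n_bits)`.
#' @export
#' @examples
#' fold_identifier(3000, 1024)  # 952
fold_identifier <- function(raw_id, n_bits) {
  if (!is.numeric(n_bits) || length(n_bits) != 1L || n_bits < 2) {
    stop_config("n_bits must be a single integer >= 2, got ", n_bits)
  }
  if (!is.numeric(raw_id) || any(raw_id < 0)) {
    stop_domain("raw environment identifiers must be non-negative")
  }
  as.integer(raw_id %% n_bits)
}

#' Generate a folded circular fingerprint with substructure provenance
#'
#' Hashes all layered atom environments of radius `0..radius` around every
#' heavy atom and folds them to `n_bits` positions. For each set bit the
#' record stores which environments it encodes: a SMARTS pattern (explicit
#' element, heavy-atom degree and formal charge; ring bonds admit the
#' aromatic alternative), the 0-based centre atom and the radius. Distinct
#' environments folded onto the same bit are all recorded and counted as
#' collisions rather than resolved.
#'
#' @param smiles SMILES string of the compound.
#' @param radius Maximum environment radius (bond hops); the default 2 gives
#'   diameter-4 fingerprints.
#' @param n_bits Folded fingerprint length (default 1024).
#' @param compound_id Identifier carried through to reports.
#' @return An object of class `fingerprint_record`: list with `compound_id`,
#'   `smiles`, `n_bits`, `radius`, integer `bits` (0/1, length `n_bits`),
#'   `provenance` (named list, 0-based bit index -> data.frame with columns
#'   `smarts`, `center`, `radius`, `raw_id`) and `collisions` (named integer
#'   vector, environments per set bit).
#' @export
featurize <- function(smiles, radius = 2L, n_bits = 1024L,
                      compound_id = smiles) {
  if (radius < 0) stop_config("radius must be >= 0")
  if (n_bits < 2) stop_config("n_bits must be >= 2")
  mol <- parse_smiles(smiles, id = compound_id)
  envs <- enumerate_environments(mol, radius)
  bits <- integer(n_bits)
  provenance <- list()
  for (e in envs) {
    bit <- fold_identifier(e$raw_id, n_bits)
    bits[bit + 1L] <- 1L
    key <- as.character(bit)
    row <- data.frame(smarts = env_smarts(mol, e$atoms, e$center),
                      center = e$center - 1L, radius = e$radius,
                      raw_id = e$raw_id, stringsAsFactors = FALSE)
    provenance[[key]] <- rbind(provenance[[key]], row)
  }
  provenance <- provenance[order(as.integer(names(provenance)))]
  collisions <- vapply(provenance, nrow, integer(1))
  structure(list(compound_id = compound_id, smiles = smiles,
                 n_bits = as.integer(n_bits), radius = as.integer(radius),
                 bits = bits, provenance = provenance,
                 collisions = collisions),
            class = "fingerprint_record")
}

# Enumerate deduplicated layered atom environments of a molecular graph.
# Returns a list of records: center (1-based), radius, atoms (sorted 1-based
# indices of the environment), raw_id (< 2^32).
enumerate_environments <- function(mol, radius) {
  n <- mol$n_atoms
  ids <- vapply(seq_len(n), function(i) {
    fnv1a32(c(mol$elem[i], mol$degree[i], mol$n_h[i], mol$charge[i] + 8L,
              as.integer(mol$in_ring[i])))
  }, numeric(1))
  env_atoms <- as.list(seq_len(n))
  seen <- character(0)
  out <- list()
  emit <- function(center, r, atoms, raw_id) {
    key <- paste(atoms, collapse = ",")
    if (key %in% seen) return(FALSE)
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- list(center = center, radius = r,
                                     atoms = atoms, raw_id = raw_id)
    TRUE
  }
  for (i in seq_len(n)) emit(i, 0L, i, ids[i])
  r <- 1L
  while (r <= radius) {
    new_ids <- ids
    new_env <- env_atoms
    for (i in seq_len(n)) {
      nb <- mol$adj[[i]]
      if (nrow(nb) == 0) next
      pairs <- cbind(nb[, "order"], ids[nb[, "nbr"]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      new_ids[i] <- fnv1a32(c(r, ids[i], as.vector(t(pairs))))
      new_env[[i]] <- sort(unique(c(env_atoms[[i]],
                                    unlist(env_atoms[nb[, "nbr"]]))))
    }
    for (i in seq_len(n)) emit(i, r, new_env[[i]], new_ids[i])
    ids <- new_ids
    env_atoms <- new_env
    r <- r + 1L
  }
  out
}

# SMARTS for the subgraph induced by `atoms`, written by depth-first
# traversal from `center` with ring-closure digits for back edges. Atom
# primitives pin element, full-molecule heavy-atom degree and formal charge;
# ring bonds are written with an aromatic alternative (-,: or =,:) because
# matching is done on the aromatic-perceived molecule while the recorded
# orders come from a kekulized structure.
env_smarts <- function(mol, atoms, center) {
  atoms <- sort(atoms)
  stopifnot(center %in% atoms)
  atom_expr <- function(i) {
    ch <- mol$charge[i]
    ch_s <- if (ch >= 0) paste0("+", ch) else as.character(ch)
    sprintf("[#%d;D%d;%s]", mol$elem[i], mol$degree[i], ch_s)
  }
  bond_expr <- function(order, ring) {
    if (order == 1) { if (ring) "-,:" else "-" }
    else if (order == 2) { if (ring) "=,:" else "=" }
    else if (order == 3) "#"
    else "~"
  }
  # adjacency restricted to the environment, neighbours in ascending order
  sub_adj <- lapply(atoms, function(i) {
    nb <- mol$adj[[i]]
    nb <- nb[nb[, "nbr"] %in% atoms, , drop = FALSE]
    nb[order(nb[, "nbr"]), , drop = FALSE]
  })
  names(sub_adj) <- as.character(atoms)

  visited <- stats::setNames(rep(FALSE, length(atoms)), as.character(atoms))
  closure_of <- list()   # atom key -> character vector of "bond+digit"
  n_digits <- 0L
  edge_used <- character(0)
  edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "-")
  order_visit <- integer(0)
  children <- list()     # atom key -> integer vector of tree children

  dfs1 <- function(i, parent) {
    ki <- as.character(i)
    visited[ki] <<- TRUE
    order_visit <<- c(order_visit, i)
    children[[ki]] <<- integer(0)
    for (row in seq_len(nrow(sub_adj[[ki]]))) {
      j <- sub_adj[[ki]][row, "nbr"]
      ek <- edge_key(i, j)
      if (ek %in% edge_used) next
      if (visited[[as.character(j)]]) {
        # back edge -> ring closure recorded at both endpoints
        edge_used <<- c(edge_used, ek)
        n_digits <<- n_digits + 1L
        dig <- if (n_digits < 10) as.character(n_digits) else paste0("%", n_digits)
        be <- bond_expr(sub_adj[[ki]][row, "order"], sub_adj[[ki]][row, "ring"])
        tag <- paste0(be, dig)
        closure_of[[ki]] <<- c(closure_of[[ki]], tag)
        closure_of[[as.character(j)]] <<- c(closure_of[[as.character(j)]], tag)
      } else {
        edge_used <<- c(edge_used, ek)
        children[[ki]] <<- c(children[[ki]], j)
        dfs1(j, i)
      }
    }
  }
  dfs1(center, 0L)

  build <- function(i) {
    ki <- as.character(i)
    s <- paste0(atom_expr(i), paste0(closure_of[[ki]], collapse = ""))
    kids <- children[[ki]]
    if (length(kids) > 0) {
      for (idx in seq_along(kids)) {
        j <- kids[idx]
        nb <- sub_adj[[ki]]
        row <- which(nb[, "nbr"] == j)[1]
        be <- bond_expr(nb[row, "order"], nb[row, "ring"])
        piece <- paste0(be, build(j))
        s <- if (idx < length(kids)) paste0(s, "(", piece, ")")
             else paste0(s, piece)
      }
    }
    s
  }
  build(center)
}

#' Map fingerprint bits back to their substructures
#'
#' For each requested bit returns the recorded SMARTS patterns when the bit
#' is set in the compound's fingerprint, or an empty pattern list with
#' `present = FALSE` when it is not (supporting analyses of absent features
#' that contribute to a prediction).
#'
#' @param record A `fingerprint_record` from [featurize()].
#' @param bit_indices Integer vector of 0-based bit indices.
#' @return A list with one entry per requested bit: `list(bit, smarts
#'   (character vector), present (logical))`.
#' @export
map_bits_to_substructures <- function(record, bit_indices) {
  stopifnot(inherits(record, "fingerprint_record"))
  bit_indices <- as.integer(bit_indices)
  if (any(bit_indices < 0 | bit_indices >= record$n_bits)) {
    stop_domain("bit index out of range [0, ", record$n_bits, ")")
  }
  lapply(bit_indices, function(b) {
    key <- as.character(b)
    if (record$bits[b + 1L] == 1L) {
      list(bit = b, smarts = record$provenance[[key]]$smarts, present = TRUE)
    } else {
      list(bit = b, smarts = character(0), present = FALSE)
    }
  })
}

#' Check that a SMARTS pattern matches a molecule
#'
#' Thin wrapper around OpenBabel SMARTS matching (via \pkg{ChemmineR}),
#' used to validate provenance patterns against their source compounds.
#'
#' @param smiles SMILES of the molecule.
#' @param smarts SMARTS pattern(s).
#' @return Logical vector: does each pattern match at least once?
#' @export
smarts_matches <- function(smiles, smarts) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
  vapply(smarts, function(p) {
    ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = FALSE)[[1]] > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' Featurize a compound table
#'
#' @param compounds Data frame with columns `id` and `smiles` (as read by
#'   [read_compounds_csv()]).
#' @inheritParams featurize
#' @return List of `fingerprint_record`s, one per row.
#' @export
featurize_batch <- function(compounds, radius = 2L, n_bits = 1024L) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  lapply(seq_len(nrow(compounds)), function(k) {
    featurize(compounds$smiles[k], radius = radius, n_bits = n_bits,
              compound_id = as.character(compounds$id[k]))
  })
}

#' Read a compound CSV (`id,smiles[,value][,label]`)
#'
#' @param path CSV file path.
#' @return Data frame with `id`, `smiles` and any optional columns.
#' @export
read_compounds_csv <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    stop_parse("compound CSV must have header columns 'id' and 'smiles'")
  }
  df
}

#' Assemble the fingerprint matrix of a record list
#'
#' @param records List of `fingerprint_record`s.
#' @return Integer matrix (rows = compounds, columns `bit0..bit{n-1}`,
#'   rownames = compound ids).
#' @export
fingerprint_matrix <- function(records) {
  n_bits <- records[[1]]$n_bits
  X <- do.call(rbind, lapply(records, `[[`, "bits"))
  rownames(X) <- vapply(records, `[[`, character(1), "compound_id")
  colnames(X) <- paste0("bit", seq_len(n_bits) - 1L)
  X
}

#' Write fingerprint matrix TSV and provenance JSON
#'
#' @param records List of `fingerprint_record`s.
#' @param tsv_path Output path for the fingerprint matrix (tab separated,
#'   `id` column followed by `bit0..bit{n-1}`).
#' @param provenance_path Optional output path for the provenance JSON
#'   (compound id -> bit -> list of `{smarts, center, radius}`).
#' @return Invisibly, the fingerprint matrix.
#' @export
write_fingerprints <- function(records, tsv_path, provenance_path = NULL) {
  X <- fingerprint_matrix(records)
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(provenance_path)) {
    prov <- lapply(records, function(r) {
      lapply(r$provenance, function(p) {
        p$raw_id <- NULL
        p
      })
    })
    names(prov) <- vapply(records, `[[`, character(1), "compound_id")
    jsonlite::write_json(prov, provenance_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(X)
}
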