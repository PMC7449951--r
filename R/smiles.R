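# Molecular graphs from SMILES. Parsing is delegated to OpenBabel through
# ChemmineR; this file only reshapes the SDF atom/bond blocks into a light
# graph structure (heavy atoms, kekulized bond orders, formal charges,
# implicit hydrogen counts, ring-bond flags) that the fingerprint generator
# consumes.

.ELEMENTS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, As = 33,
  Se = 34, Br = 35, I = 53, Sn = 50, Sb = 51, Te = 52, Pt = 78, Au = 79,
  Hg = 80
)

# usual organic-subset valences; used only to estimate implicit H counts
.DEFAULT_VALENCE <- c(`5` = 3, `6` = 4, `7` = 3, `8` = 2, `9` = 1, `14` = 4,
                      `15` = 3, `16` = 2, `17` = 1, `35` = 1, `53` = 1)

# MDL atom-block charge codes (field 4): 1..7 -> +3..-3, 0 -> neutral
.MDL_CHARGE <- c(3, 2, 1, 0, -1, -2, -3)

mdl_charge <- function(code) {
  ifelse(code >= 1 & code <= 7, .MDL_CHARGE[pmax(code, 1)], 0)
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Uses OpenBabel (via \pkg{ChemmineR}) to interpret the SMILES, then strips
#' explicit hydrogens and derives the per-atom attributes needed for circular
#' fingerprint generation.
#'
#' @param smiles A single SMILES string.
#' @param id Identifier used in error messages (e.g. the input row id).
#' @return An object of class `mol_graph`: a list with `n_atoms`, integer
#'   vectors `elem` (atomic numbers), `charge`, `n_h` (implicit plus stripped
#'   explicit hydrogens), `degree` (heavy-atom degree), logical `in_ring`,
#'   a bond table `bonds` (columns `a`, `b`, `order`, `ring`) and adjacency
#'   list `adj` (each entry: matrix with columns `nbr`, `order`, `ring`).
#' @export
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) stop_parse("cannot parse SMILES for '", id, "': ",
                                   conditionMessage(e))
  )
  if (length(sdf) < 1L || !any(ChemmineR::validSDF(sdf))) {
    # ChemmineR's SDF reader cannot represent bond-free molecules (e.g. a
    # single heavy atom); read the molfile atom lines directly in that case
    return(parse_bondfree(smiles, id))
  }
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  sym <- sub("_.*$", "", rownames(ab))
  elem <- unname(.ELEMENTS[sym])
  if (anyNA(elem)) {
    stop_parse("unknown element '", sym[which(is.na(elem))[1]],
               "' in SMILES for '", id, "'")
  }
  # atom-block fields: C1=x, C2=y, C3=z, (symbol), C5=mass diff, C6=charge code
  charge <- mdl_charge(as.numeric(ab[, "C6"]))
  n <- length(elem)
  if (is.null(dim(bb)) && length(bb) > 0) bb <- matrix(bb, nrow = 1,
                                                       dimnames = list(NULL, names(bb)))
  if (length(bb) == 0 || nrow(bb) == 0) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  } else {
    bonds <- data.frame(a = as.integer(bb[, "C1"]), b = as.integer(bb[, "C2"]),
                        order = as.integer(bb[, "C3"]))
  }
  # aromatic bond order 4 should not appear (OpenBabel kekulizes); guard anyway
  bonds$order[bonds$order == 4L] <- 1L

  # strip explicit hydrogens, crediting them to the bonded heavy atom
  is_h <- elem == 1L
  extra_h <- integer(n)
  if (any(is_h)) {
    for (k in seq_len(nrow(bonds))) {
      if (is_h[bonds$a[k]] && !is_h[bonds$b[k]]) extra_h[bonds$b[k]] <- extra_h[bonds$b[k]] + 1L
      if (is_h[bonds$b[k]] && !is_h[bonds$a[k]]) extra_h[bonds$a[k]] <- extra_h[bonds$a[k]] + 1L
    }
    keep <- which(!is_h)
    remap <- match(seq_len(n), keep)
    bonds <- bonds[!is_h[bonds$a] & !is_h[bonds$b], , drop = FALSE]
    bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
    elem <- elem[keep]; charge <- charge[keep]; extra_h <- extra_h[keep]
    n <- length(keep)
  }

  degree <- tabulate(c(bonds$a, bonds$b), nbins = n)
  bond_sum <- rep(0L, n)
  for (k in seq_len(nrow(bonds))) {
    bond_sum[bonds$a[k]] <- bond_sum[bonds$a[k]] + bonds$order[k]
    bond_sum[bonds$b[k]] <- bond_sum[bonds$b[k]] + bonds$order[k]
  }
  val <- .DEFAULT_VALENCE[as.character(elem)]
  val[is.na(val)] <- 0
  # charge raises (cations) or lowers (anions) the H capacity for N/O/C-like
  # atoms; hypervalent S/P fall back to the next standard valence
  val <- val + charge
  hyper <- elem %in% c(15L, 16L) & bond_sum > val
  val[hyper] <- ifelse(bond_sum[hyper] <= val[hyper] + 2, val[hyper] + 2, val[hyper] + 4)
  n_h <- pmax(0L, as.integer(val - bond_sum)) + extra_h

  bonds$ring <- ring_bonds(n, bonds)
  in_ring <- rep(FALSE, n)
  in_ring[c(bonds$a[bonds$ring], bonds$b[bonds$ring])] <- TRUE

  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- matrix(integer(), 0, 3,
                                           dimnames = list(NULL, c("nbr", "order", "ring")))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- rbind(adj[[a]], c(b, bonds$order[k], as.integer(bonds$ring[k])))
    adj[[b]] <- rbind(adj[[b]], c(a, bonds$order[k], as.integer(bonds$ring[k])))
  }

  structure(list(smiles = smiles, n_atoms = n, elem = elem, charge = charge,
                 n_h = n_h, degree = degree, in_ring = in_ring,
                 bonds = bonds, adj = adj),
            class = "mol_graph")
}

# Molecules without bonds between heavy atoms: take the V2000 molfile from
# OpenBabel and read the atom lines directly.
parse_bondfree <- function(smiles, id) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_parse("cannot parse SMILES for '", id, "': ChemmineOB unavailable")
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tm\n")),
    error = function(e) stop_parse("cannot parse SMILES for '", id, "': ",
                                   conditionMessage(e))
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop_parse("cannot parse SMILES for '", id,
                                    "': invalid structure")
  n_at <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_at) || n_at < 1) {
    stop_parse("cannot parse SMILES for '", id, "': invalid structure")
  }
  if (!is.na(n_bd) && n_bd > 0) {
    stop_parse("cannot parse SMILES for '", id, "': unreadable structure")
  }
  fields <- strsplit(trimws(lines[5:(4 + n_at)]), "\\s+")
  sym <- vapply(fields, `[[`, character(1), 4)
  chg_code <- vapply(fields, function(f) as.integer(f[6]), integer(1))
  elem <- unname(.ELEMENTS[sym])
  if (anyNA(elem)) stop_parse("unknown element in SMILES for '", id, "'")
  charge <- mdl_charge(chg_code)
  keep <- which(elem != 1L)
  elem <- elem[keep]; charge <- charge[keep]
  n <- length(elem)
  if (n == 0) stop_parse("cannot parse SMILES for '", id, "': no heavy atoms")
  val <- .DEFAULT_VALENCE[as.character(elem)]
  val[is.na(val)] <- 0
  n_h <- pmax(0L, as.integer(val + charge))
  bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                      ring = logical())
  adj <- lapply(seq_len(n), function(i) {
    matrix(integer(), 0, 3, dimnames = list(NULL, c("nbr", "order", "ring")))
  })
  structure(list(smiles = smiles, n_atoms = n, elem = elem, charge = charge,
                 n_h = n_h, degree = rep(0L, n), in_ring = rep(FALSE, n),
                 bonds = bonds, adj = adj),
            class = "mol_graph")
}

# A bond is a ring bond iff its endpoints stay connected after removing it.
ring_bonds <- function(n_atoms, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  out <- logical(m)
  for (k in seq_len(m)) {
    reach <- rep(FALSE, n_atoms)
    reach[bonds$a[k]] <- TRUE
    frontier <- bonds$a[k]
    while (length(frontier) > 0 && !reach[bonds$b[k]]) {
      nxt <- integer(0)
      for (j in seq_len(m)) {
        if (j == k) next
        if (reach[bonds$a[j]] && !reach[bonds$b[j]]) nxt <- c(nxt, bonds$b[j])
        if (reach[bonds$b[j]] && !reach[bonds$a[j]]) nxt <- c(nxt, bonds$a[j])
      }
      nxt <- unique(nxt)
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    out[k] <- reach[bonds$b[k]]
  }
  out
}
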