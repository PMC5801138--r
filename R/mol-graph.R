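# Core molecular-graph container: a hydrogen-suppressed labelled graph.
# Atoms carry element, formal charge, implicit-H count, aromatic flag and the
# derived valence-electron count; bonds carry integer order (1/2/3) plus an
# aromatic flag. All atom indices are 1-based internally (SDF input is already
# 1-based; SMILES input is translated at the parser boundary).

# periodic-table lookups used by the valence model and the Kier-Hall deltas
.ELEMENT_Z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Zn = 30, Se = 34, Br = 35, I = 53
)

# valence electrons (periodic-table group)
.ELEMENT_ZV <- c(
  H = 1, He = 2, Li = 1, Be = 2, B = 3, C = 4, N = 5, O = 6, F = 7, Ne = 8,
  Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2, Zn = 2, Se = 6, Br = 7, I = 7
)

# default valence used to infer implicit hydrogens from an SDF connection table
.DEFAULT_VALENCE <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Construct a molecular graph
#'
#' Builds the hydrogen-suppressed labelled graph that every descriptor in the
#' package operates on. Explicit hydrogen atoms may be present (e.g. directly
#' after parsing); [preprocess()] folds them into per-atom implicit counts.
#'
#' @param elements character vector of atomic symbols, one per atom.
#' @param bonds two- or three-column matrix (or data.frame) of bonds: atom
#'   index, atom index, bond order. Order 4 is interpreted as aromatic.
#'   May have zero rows.
#' @param charges integer formal charges, recycled to the atom count.
#' @param h implicit hydrogen counts per atom, or `NULL` to infer them from
#'   the standard valence model (element default valence, charge-adjusted,
#'   minus the bond-order sum).
#' @param aromatic logical per-atom aromatic flags, or `NULL` (all `FALSE`;
#'   [preprocess()] can perceive them).
#' @param name molecule name label.
#' @return An object of class `mol_graph` with components `atoms`
#'   (data.frame: `element`, `Z`, `charge`, `h`, `aromatic`, `Zv`), `bonds`
#'   (data.frame: `i`, `j`, `order`, `aromatic`) and `name`.
#' @examples
#' # propane skeleton
#' m <- mol_graph(c("C", "C", "C"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' heavy_degree(m, 2)
#' @export
mol_graph <- function(elements, bonds = NULL, charges = 0L, h = NULL,
                      aromatic = NULL, name = "") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("molecule must have at least one atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- matrix(numeric(0), ncol = 3)
  } else {
    bonds <- as.matrix(bonds)
    if (ncol(bonds) == 2L) bonds <- cbind(bonds, 1)
  }
  bi <- as.integer(bonds[, 1]); bj <- as.integer(bonds[, 2])
  border <- as.numeric(bonds[, 3])
  barom <- border == 4
  border[barom] <- 1
  if (any(bi == bj)) stop("self-loops are not allowed")
  if (length(bi) && (min(c(bi, bj)) < 1L || max(c(bi, bj)) > n))
    stop("bond refers to an atom index outside the molecule")
  key <- paste(pmin(bi, bj), pmax(bi, bj))
  if (anyDuplicated(key)) stop("duplicate bonds are not allowed")

  Z <- unname(.ELEMENT_Z[elements])
  if (anyNA(Z)) stop("unsupported element(s): ",
                     paste(unique(elements[is.na(Z)]), collapse = ", "))
  Zv <- unname(.ELEMENT_ZV[elements])
  charges <- rep_len(as.integer(charges), n)
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  aromatic <- rep_len(as.logical(aromatic), n)

  atoms <- data.frame(element = elements, Z = Z, charge = charges,
                      h = 0L, aromatic = aromatic, Zv = Zv,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border, aromatic = barom)
  m <- structure(list(atoms = atoms, bonds = bonds, name = as.character(name)),
                 class = "mol_graph")
  m$atoms$h <- if (is.null(h)) implicit_hydrogens(m) else rep_len(as.integer(h), n)
  m
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atom(s), %d bond(s)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# charge-adjusted default valence; metals and unknown elements get 0 so they
# never acquire phantom hydrogens
effective_valence <- function(element, charge) {
  v <- .DEFAULT_VALENCE[element]
  v[is.na(v)] <- 0
  right <- element %in% c("N", "O", "P", "S", "F", "Cl", "Br", "I")
  v[right] <- v[right] + charge[right]
  v[element == "C"] <- v[element == "C"] - abs(charge[element == "C"])
  v[element == "B"] <- v[element == "B"] - charge[element == "B"]
  pmax(unname(v), 0)
}

# implicit hydrogens from the valence model: default valence minus the sum of
# bond orders at the atom (aromatic bonds must already be kekulized; parser
# output is)
implicit_hydrogens <- function(mol) {
  n <- n_atoms(mol)
  bsum <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      bsum[b$i] <- bsum[b$i] + b$order
      bsum[b$j] <- bsum[b$j] + b$order
    }
  }
  as.integer(pmax(0, round(effective_valence(mol$atoms$element, mol$atoms$charge) - bsum)))
}

#' Heavy-atom degree of an atom
#'
#' The number of heavy-atom neighbours, i.e. the Kier-Hall simple delta.
#'
#' @param mol a [mol_graph()].
#' @param atom 1-based atom index.
#' @return Integer degree.
#' @export
heavy_degree <- function(mol, atom) {
  atom <- as.integer(atom)
  if (atom < 1L || atom > n_atoms(mol)) stop("atom index out of range")
  heavy <- mol$atoms$element != "H"
  sum((mol$bonds$i == atom & heavy[mol$bonds$j]) |
      (mol$bonds$j == atom & heavy[mol$bonds$i]))
}

# adjacency list over all atoms (indices of neighbours)
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# igraph view of the (heavy or full) graph, vertex names = atom indices
mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else data.frame(i = integer(0), j = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol)))
  )
}

# connected components as a list of atom-index vectors
mol_components <- function(mol) {
  comp <- igraph::components(mol_igraph(mol))
  split(seq_len(n_atoms(mol)), comp$membership)
}

is_connected_mol <- function(mol) {
  n_atoms(mol) == 1L || igraph::is_connected(mol_igraph(mol))
}

# induced subgraph on a set of atoms (bond orders preserved); atom order
# follows sort(keep)
induced_subgraph_mol <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- match(seq_len(n_atoms(mol)), keep)
  b <- mol$bonds[mol$bonds$i %in% keep & mol$bonds$j %in% keep, , drop = FALSE]
  out <- mol
  out$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds <- data.frame(i = map[b$i], j = map[b$j],
                          order = b$order, aromatic = b$aromatic)
  out
}

#' Mark or test a record-level parse failure
#'
#' Unparseable input records become placeholder molecules rather than aborting
#' a batch; every descriptor evaluated on a placeholder yields a
#' [missing_value()] with reason `"parse_failure"`.
#'
#' @param mol a `mol_graph` (or placeholder).
#' @return `is_parse_failure()` returns a logical scalar.
#' @export
is_parse_failure <- function(mol) isTRUE(attr(mol, "parse_failure"))

parse_failure_mol <- function(name = "", message = "unparseable record") {
  m <- mol_graph("C", name = name)
  attr(m, "parse_failure") <- TRUE
  attr(m, "parse_message") <- message
  m
}
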