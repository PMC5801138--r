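# Per-descriptor molecule preprocessing: hydrogen handling, desalting,
# kekulization and aromaticity perception. All in-scope descriptors operate on
# the hydrogen-suppressed graph, so "remove" is the default hydrogen mode.

#' Preprocessing policy
#'
#' @param explicit_hydrogens `"remove"` folds explicit H atoms into per-atom
#'   implicit counts (the convention every descriptor here assumes); `"add"`
#'   expands implicit counts into explicit H atoms.
#' @param kekulize assign alternating single/double bond orders within
#'   aromatic ring systems.
#' @param perceive_aromaticity recompute per-atom/per-bond aromatic flags with
#'   the package's ring-based Hückel model (see the methods vignette).
#' @param desalt keep only the largest connected component by heavy-atom
#'   count (ties broken by lowest atom index).
#' @return A `preprocess_policy` object.
#' @export
preprocess_policy <- function(explicit_hydrogens = c("remove", "add"),
                              kekulize = FALSE,
                              perceive_aromaticity = TRUE,
                              desalt = FALSE) {
  structure(list(explicit_hydrogens = match.arg(explicit_hydrogens),
                 kekulize = isTRUE(kekulize),
                 perceive_aromaticity = isTRUE(perceive_aromaticity),
                 desalt = isTRUE(desalt)),
            class = "preprocess_policy")
}

#' Preprocess a molecule
#'
#' Applies the hydrogen mode, optional desalting, optional kekulization and
#' aromaticity perception of `policy`. Deterministic and idempotent for a
#' fixed policy.
#'
#' @param mol a [mol_graph()].
#' @param policy a [preprocess_policy()].
#' @return The preprocessed `mol_graph`. The aromaticity model used is
#'   recorded in `attr(, "aromaticity_model")`.
#' @export
preprocess <- function(mol, policy = preprocess_policy()) {
  stopifnot(inherits(mol, "mol_graph"))
  if (is_parse_failure(mol)) return(mol)
  if (policy$desalt) {
    comps <- mol_components(mol)
    heavy_n <- vapply(comps, function(cc) sum(mol$atoms$element[cc] != "H"), 0)
    mol <- induced_subgraph_mol(mol, comps[[which.max(heavy_n)]])
  }
  mol <- if (policy$explicit_hydrogens == "remove") remove_explicit_h(mol) else add_explicit_h(mol)
  if (policy$perceive_aromaticity) mol <- perceive_aromaticity_(mol)
  if (policy$kekulize) mol <- kekulize_(mol)
  attr(mol, "aromaticity_model") <- if (policy$perceive_aromaticity) "sssr-huckel" else "as-input"
  attr(mol, "parse_failure") <- attr(mol, "parse_failure")
  mol
}

remove_explicit_h <- function(mol) {
  is_h <- mol$atoms$element == "H"
  if (!any(is_h)) return(mol)
  extra_h <- integer(n_atoms(mol))
  keep_bond <- rep(TRUE, nrow(mol$bonds))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (is_h[i] && !is_h[j]) { extra_h[j] <- extra_h[j] + 1L; keep_bond[k] <- FALSE }
      else if (is_h[j] && !is_h[i]) { extra_h[i] <- extra_h[i] + 1L; keep_bond[k] <- FALSE }
      else if (is_h[i] && is_h[j]) keep_bond[k] <- FALSE
    }
  }
  mol$bonds <- mol$bonds[keep_bond, , drop = FALSE]
  mol$atoms$h <- mol$atoms$h + extra_h
  out <- induced_subgraph_mol(mol, which(!is_h))
  if (n_atoms(out) == 0L || all(mol$atoms$element == "H"))
    stop("molecule empty after hydrogen suppression")
  out
}

add_explicit_h <- function(mol) {
  nh <- mol$atoms$h
  if (!any(nh > 0L)) return(mol)
  n0 <- n_atoms(mol)
  new_bonds <- mol$bonds
  elements <- mol$atoms$element
  charges <- mol$atoms$charge
  arom <- mol$atoms$aromatic
  nxt <- n0
  for (v in seq_len(n0)) {
    for (t in seq_len(nh[v])) {
      nxt <- nxt + 1L
      elements <- c(elements, "H")
      charges <- c(charges, 0L)
      arom <- c(arom, FALSE)
      new_bonds <- rbind(new_bonds,
                         data.frame(i = v, j = nxt, order = 1, aromatic = FALSE))
    }
  }
  out <- mol_graph(elements, as.matrix(new_bonds[, c("i", "j", "order")]),
                   charges = charges, h = rep(0L, nxt),
                   aromatic = arom, name = mol$name)
  out$bonds$aromatic <- new_bonds$aromatic
  out
}

# ---- ring perception -------------------------------------------------------

# Smallest set of smallest rings as a minimum cycle basis (Horton selection:
# candidate cycles through each vertex/edge, greedily chosen independent over
# GF(2) in order of length). Returns a list of atom-index vectors in ring
# order.
sssr_rings <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(list())
  g <- mol_igraph(mol)
  ncomp <- igraph::components(g)$no
  mu <- nb - n + ncomp
  if (mu <= 0L) return(list())
  dm <- igraph::distances(g)
  # candidate cycles: v + shortest paths to both ends of a non-incident edge
  cand <- list()
  for (v in seq_len(n)) {
    sp <- igraph::shortest_paths(g, from = v, to = igraph::V(g))$vpath
    for (k in seq_len(nb)) {
      x <- mol$bonds$i[k]; y <- mol$bonds$j[k]
      if (v == x || v == y) next
      dx <- dm[v, x]; dy <- dm[v, y]
      if (!is.finite(dx) || !is.finite(dy)) next
      px <- as.integer(sp[[x]]); py <- as.integer(sp[[y]])
      # paths must be disjoint except at v for a simple cycle
      if (length(intersect(px[-1], py[-1])) > 0L) next
      cyc <- c(px, rev(py)[-length(py)])
      cand[[length(cand) + 1L]] <- cyc
    }
  }
  if (!length(cand)) return(list())
  lens <- vapply(cand, length, 0L)
  cand <- cand[order(lens)]
  ekey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  cyc_vec <- function(cyc) {
    m <- length(cyc)
    a <- cyc; b <- c(cyc[-1], cyc[1])
    kk <- match(paste(pmin(a, b), pmax(a, b)), ekey)
    v <- logical(nb); v[kk] <- TRUE; v
  }
  basis <- list(); rings <- list(); seen <- character(0)
  for (cyc in cand) {
    key <- paste(sort(cyc), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    vec <- cyc_vec(cyc)
    red <- vec
    for (b in basis) {
      pivot <- which(b)[1]
      if (red[pivot]) red <- xor(red, b)
    }
    if (any(red)) {
      # store in reduced-echelon-ish form: keep original vec, order by pivot
      basis[[length(basis) + 1L]] <- red
      rings[[length(rings) + 1L]] <- cyc
      if (length(rings) == mu) break
    }
  }
  rings
}

# ---- aromaticity -----------------------------------------------------------

# Ring-based Hückel-style perception on the SSSR: a ring is aromatic when
# every ring atom can contribute to the pi system (a double bond anywhere, or
# a lone pair on N/O/S) and the ring's pi-electron count is 4k+2. Fused
# aromatic systems emerge ring-by-ring (each benzenoid ring passes on its
# own). Flags are set on atoms and on ring bonds of aromatic rings.
perceive_aromaticity_ <- function(mol) {
  # input claims survive as pi-capability hints: an atom flagged aromatic on
  # input (e.g. a graph built with order-4 bonds) can contribute one pi
  # electron even before kekulization assigns it a double bond
  claimed <- mol$atoms$aromatic
  if (nrow(mol$bonds)) {
    ab <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
    claimed[unique(c(ab$i, ab$j))] <- TRUE
  }
  mol$atoms$aromatic <- rep(FALSE, n_atoms(mol))
  mol$bonds$aromatic <- rep(FALSE, max(1L, nrow(mol$bonds)))[seq_len(nrow(mol$bonds))]
  rings <- sssr_rings(mol)
  if (!length(rings)) return(mol)
  has_double <- logical(n_atoms(mol))
  if (nrow(mol$bonds)) {
    db <- mol$bonds[mol$bonds$order == 2, , drop = FALSE]
    has_double[unique(c(db$i, db$j))] <- TRUE
  }
  ekey <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
  for (ring in rings) {
    pi_e <- 0L; ok <- TRUE
    for (v in ring) {
      el <- mol$atoms$element[v]
      if (has_double[v] || (claimed[v] && el == "C") ||
          (claimed[v] && el == "N" && mol$atoms$h[v] == 0L &&
           mol$atoms$charge[v] == 0L)) {
        pi_e <- pi_e + 1L        # double bond or delocalized C / pyridine N
      } else if (el %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L        # lone-pair donor (pyrrole/furan/thiophene N,O,S)
      } else {
        ok <- FALSE; break      # sp3 carbon in ring: not aromatic
      }
    }
    if (ok && pi_e %% 4L == 2L) {
      mol$atoms$aromatic[ring] <- TRUE
      a <- ring; b <- c(ring[-1], ring[1])
      kk <- match(paste(pmin(a, b), pmax(a, b)), ekey)
      mol$bonds$aromatic[kk] <- TRUE
    }
  }
  mol
}

# ---- kekulization ----------------------------------------------------------

# Assign alternating orders within aromatic systems whose bonds are not
# already kekulized: find a perfect matching (backtracking) over aromatic
# atoms that need one double bond each; lone-pair donors (N-H, O, S) are
# excluded from the matching.
kekulize_ <- function(mol) {
  arom_atoms <- which(mol$atoms$aromatic)
  if (!length(arom_atoms)) return(mol)
  has_double <- logical(n_atoms(mol))
  if (nrow(mol$bonds)) {
    db <- mol$bonds[mol$bonds$order == 2, , drop = FALSE]
    has_double[unique(c(db$i, db$j))] <- TRUE
  }
  needs <- vapply(arom_atoms, function(v) {
    el <- mol$atoms$element[v]
    if (has_double[v]) return(FALSE)
    if (el == "C") return(TRUE)
    if (el == "N" && mol$atoms$h[v] == 0L && mol$atoms$charge[v] == 0L) return(TRUE)
    FALSE
  }, TRUE)
  need_set <- arom_atoms[needs]
  if (!length(need_set)) return(mol)
  arom_bond_idx <- which(mol$bonds$aromatic &
                         mol$bonds$i %in% need_set & mol$bonds$j %in% need_set)
  nbrs <- lapply(need_set, function(v) {
    k <- arom_bond_idx[mol$bonds$i[arom_bond_idx] == v | mol$bonds$j[arom_bond_idx] == v]
    setdiff(c(mol$bonds$i[k], mol$bonds$j[k]), v)
  })
  names(nbrs) <- as.character(need_set)
  matched <- integer(0)  # named: atom -> partner
  match_rec <- function(todo, matched) {
    if (!length(todo)) return(matched)
    v <- todo[1]
    if (as.character(v) %in% names(matched)) return(match_rec(todo[-1], matched))
    for (w in nbrs[[as.character(v)]]) {
      if (as.character(w) %in% names(matched)) next
      m2 <- matched
      m2[as.character(v)] <- w
      m2[as.character(w)] <- v
      res <- match_rec(todo[-1], m2)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- match_rec(need_set, matched)
  if (is.null(res)) stop("kekulization failed: no perfect matching in aromatic system")
  pairs <- unique(t(apply(cbind(as.integer(names(res)), as.integer(res)), 1, sort)))
  for (r in seq_len(nrow(pairs))) {
    k <- which((mol$bonds$i == pairs[r, 1] & mol$bonds$j == pairs[r, 2]) |
               (mol$bonds$i == pairs[r, 2] & mol$bonds$j == pairs[r, 1]))
    mol$bonds$order[k] <- 2
  }
  mol
}
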