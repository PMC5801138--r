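# The in-scope 2D descriptor families as direct functions of a
# hydrogen-suppressed molecular graph. Each returns numeric value(s) or a
# typed missing_value. The calculator presets in presets.R wrap these with
# shared-intermediate caching.

# exact rational accumulation for the modified Zagreb sums: numerators and
# denominators stay integer until the final division, so values like 4/3 are
# reproduced exactly rather than as a drifted float sum
rational_sum <- function(numers, denoms) {
  stopifnot(length(numers) == length(denoms))
  num <- 0; den <- 1
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  for (k in seq_along(numers)) {
    num <- num * denoms[k] + numers[k] * den
    den <- den * denoms[k]
    g <- gcd(num, den)
    if (g > 1) { num <- num / g; den <- den / g }
  }
  num / den
}

#' Atom counts
#'
#' Heavy-atom, hydrogen and per-element tallies, halogen total, and
#' ring-topology counts (spiro atoms: shared by two rings meeting in exactly
#' one atom; bridgehead atoms: endpoints of a multi-bond path shared by two
#' rings).
#'
#' @param mol a hydrogen-suppressed [mol_graph()].
#' @param rings optional precomputed SSSR ring list.
#' @return Named list of 16 integers: `nAtom` (heavy + hydrogens),
#'   `nHeavyAtom`, `nH`, `nB`, `nC`, `nN`, `nO`, `nS`, `nP`, `nF`, `nCl`,
#'   `nBr`, `nI`, `nX`, `nSpiro`, `nBridgehead`.
#' @export
atom_counts <- function(mol, rings = NULL) {
  el <- mol$atoms$element
  heavy <- el != "H"
  n_h <- sum(mol$atoms$h) + sum(!heavy)
  per <- vapply(c("B", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
                function(e) sum(el == e), 0L)
  nX <- sum(per[c("F", "Cl", "Br", "I")])
  names(per) <- paste0("n", names(per))
  if (is.null(rings)) rings <- sssr_rings(mol)
  spiro <- integer(0); bridge <- integer(0)
  if (length(rings) >= 2L) {
    for (a in seq_len(length(rings) - 1L)) for (b in (a + 1L):length(rings)) {
      shared <- intersect(rings[[a]], rings[[b]])
      if (length(shared) == 1L) {
        spiro <- c(spiro, shared)
      } else if (length(shared) >= 3L) {
        # shared path of >= 2 bonds: its endpoints are bridgeheads
        sub <- mol$bonds[mol$bonds$i %in% shared & mol$bonds$j %in% shared, ]
        degI <- table(factor(c(sub$i, sub$j), levels = shared))
        bridge <- c(bridge, as.integer(shared[degI == 1L]))
      }
    }
  }
  as.list(c(nAtom = sum(heavy) + n_h, nHeavyAtom = sum(heavy), nH = n_h,
            per, nX = nX,
            nSpiro = length(unique(spiro)),
            nBridgehead = length(unique(bridge))))
}

#' Zagreb indices
#'
#' First and second Zagreb indices and their modified (inverse) forms:
#' Zagreb1 = \eqn{\sum_i \delta_i^2}, Zagreb2 = \eqn{\sum_{(u,v) \in E}
#' \delta_u \delta_v}, mZagreb1 = \eqn{\sum_i \delta_i^{-2}}, mZagreb2 =
#' \eqn{\sum_{(u,v) \in E} (\delta_u \delta_v)^{-1}}. The modified sums are
#' accumulated as exact rationals, so values such as 4/3 are exact.
#'
#' @inheritParams atom_counts
#' @param delta optional precomputed [delta_vector()].
#' @return Named list: `Zagreb1`, `Zagreb2`, `mZagreb1`, `mZagreb2`.
#' @export
zagreb_indices <- function(mol, delta = NULL) {
  d <- if (is.null(delta)) delta_vector(mol) else delta
  e <- mol$bonds
  z2 <- if (nrow(e)) sum(d[e$i] * d[e$j]) else 0
  pos <- d[d > 0]
  mz1 <- if (length(pos)) rational_sum(rep(1, length(pos)), pos^2) else 0
  mz2 <- if (nrow(e)) rational_sum(rep(1, nrow(e)), d[e$i] * d[e$j]) else 0
  list(Zagreb1 = sum(d^2), Zagreb2 = z2, mZagreb1 = mz1, mZagreb2 = mz2)
}

#' Wiener indices
#'
#' `WPath` is the Wiener path number (half-sum of the topological distance
#' matrix); `WPol` the polarity number (atom pairs at distance exactly 3).
#'
#' @inheritParams atom_counts
#' @param dist optional precomputed [distance_matrix()] bundle.
#' @return Named list `WPath`, `WPol`, or a [missing_value()] if
#'   disconnected.
#' @export
wiener <- function(mol, dist = NULL) {
  if (is.null(dist)) dist <- distance_matrix(mol)
  if (is_missing(dist)) return(dist)
  D <- dist$matrix
  list(WPath = sum(D) / 2, WPol = sum(D == 3) / 2)
}

#' Balaban's J index
#'
#' \eqn{J = \frac{M}{\mu + 1} \sum_{(u,v) \in E} (s_u s_v)^{-1/2}} with M the
#' bond count, \eqn{\mu = M - n + 1} the cyclomatic number and \eqn{s_i} the
#' distance-matrix row sums, on the hydrogen-suppressed graph.
#'
#' @inheritParams wiener
#' @return Numeric, or a [missing_value()] (single atom: `"empty_graph"`,
#'   disconnected: `"disconnected"`).
#' @export
balaban_j <- function(mol, dist = NULL) {
  n <- n_atoms(mol)
  if (n < 2L) return(missing_value("empty_graph", "Balaban J needs >= 2 atoms"))
  if (is.null(dist)) dist <- distance_matrix(mol)
  if (is_missing(dist)) return(dist)
  s <- rowSums(dist$matrix)
  M <- nrow(mol$bonds)
  mu <- M - n + 1L
  M / (mu + 1) * sum((s[mol$bonds$i] * s[mol$bonds$j])^(-0.5))
}

#' Kier-Hall chi connectivity index
#'
#' Enumerates all connected subgraphs of the requested shape class and order
#' by depth-first search and sums \eqn{\prod_{v \in S} \delta_v^{-1/2}} over
#' them (valence variants use the valence delta). Averaged variants divide by
#' the subgraph count.
#'
#' @inheritParams atom_counts
#' @param kind `"path"`, `"chain"` (ring-containing), `"cluster"` or
#'   `"path_cluster"`.
#' @param order subgraph edge count m (m = 0: single atoms, path kind).
#' @param variant `"simple"`, `"valence"`, `"averaged_simple"`,
#'   `"averaged_valence"`.
#' @param subgraphs,delta,delta_v optional precomputed intermediates.
#' @return Numeric; 0 when no subgraph of the class exists (plain variants),
#'   a [missing_value()] (`"divide_by_zero"`) for averaged variants with no
#'   subgraphs or when a delta is zero.
#' @export
chi <- function(mol, kind = c("path", "chain", "cluster", "path_cluster"),
                order = 1L,
                variant = c("simple", "valence", "averaged_simple", "averaged_valence"),
                subgraphs = NULL, delta = NULL, delta_v = NULL) {
  kind <- match.arg(kind)
  variant <- match.arg(variant)
  if (is.null(subgraphs)) subgraphs <- classified_edge_subgraphs(mol, order)
  w <- if (variant %in% c("valence", "averaged_valence")) {
    if (is.null(delta_v)) valence_delta_vector(mol) else delta_v
  } else {
    if (is.null(delta)) delta_vector(mol) else delta
  }
  subs <- Filter(function(s) s$kind == kind, subgraphs)
  averaged <- variant %in% c("averaged_simple", "averaged_valence")
  if (!length(subs)) {
    if (averaged)
      return(missing_value("divide_by_zero", "no subgraphs of requested class"))
    return(0)
  }
  terms <- vapply(subs, function(s) {
    dv <- w[s$vertices]
    if (any(dv <= 0)) return(NA_real_)
    prod(dv^(-0.5))
  }, 0)
  if (anyNA(terms))
    return(missing_value("divide_by_zero", "zero delta in a subgraph"))
  total <- sum(terms)
  if (averaged) total / length(subs) else total
}

#' Kappa shape indices
#'
#' With A the heavy-atom count and \eqn{P_m} the number of m-bond paths:
#' \eqn{\kappa_1 = A (A-1)^2 / P_1^2}, \eqn{\kappa_2 = (A-1)(A-2)^2 / P_2^2},
#' \eqn{\kappa_3 = (A-1)(A-3)^2 / P_3^2} for odd A and
#' \eqn{(A-3)(A-2)^2 / P_3^2} for even A (plain Kier kappa, no alpha
#' correction).
#'
#' @inheritParams atom_counts
#' @return Named list `Kier1`, `Kier2`, `Kier3`; entries are
#'   [missing_value()]s when the molecule is too small (`"empty_graph"`) or a
#'   path count vanishes (`"divide_by_zero"`).
#' @export
kappa_shape <- function(mol) {
  A <- sum(mol$atoms$element != "H")
  pcount <- function(m) {
    subs <- classified_edge_subgraphs(mol, m)
    sum(vapply(subs, function(s) s$kind == "path", TRUE))
  }
  kap <- function(min_atoms, num_fn, m) {
    if (A < min_atoms)
      return(missing_value("empty_graph", sprintf("kappa%d needs >= %d heavy atoms", m, min_atoms)))
    P <- pcount(m)
    if (P == 0L)
      return(missing_value("divide_by_zero", sprintf("no %d-bond paths", m)))
    num_fn(A) / P^2
  }
  list(
    Kier1 = kap(3L, function(A) A * (A - 1)^2, 1L),
    Kier2 = kap(4L, function(A) (A - 1) * (A - 2)^2, 2L),
    Kier3 = kap(4L, function(A) if (A %% 2 == 1) (A - 1) * (A - 3)^2 else (A - 3) * (A - 2)^2, 3L)
  )
}

#' Eccentric connectivity index
#'
#' \eqn{\xi = \sum_i \delta_i \, \mathrm{ecc}(i)} where ecc(i) is the
#' graph eccentricity (maximum distance-matrix row entry).
#'
#' @inheritParams wiener
#' @param delta optional precomputed [delta_vector()].
#' @return Integer, or a [missing_value()] if disconnected.
#' @export
eccentric_connectivity <- function(mol, dist = NULL, delta = NULL) {
  if (is.null(dist)) dist <- distance_matrix(mol)
  if (is_missing(dist)) return(dist)
  d <- if (is.null(delta)) delta_vector(mol) else delta
  ecc <- apply(dist$matrix, 1, max)
  sum(d * ecc)
}

#' Ring size counts
#'
#' Number of perceived SSSR rings of each requested size. Sizes beyond the
#' default 3-12 range (e.g. macrolide 14-16 rings) are requested by
#' extending `sizes`; counting is over SSSR members only.
#'
#' @inheritParams atom_counts
#' @param sizes integer vector of ring sizes to count.
#' @return Named integer list (`nRing3`, `nRing4`, ...).
#' @export
ring_counts <- function(mol, sizes = 3:12, rings = NULL) {
  if (is.null(rings)) rings <- sssr_rings(mol)
  ring_sizes <- vapply(rings, length, 0L)
  out <- lapply(sizes, function(s) sum(ring_sizes == s))
  names(out) <- paste0("nRing", sizes)
  out
}

#' Molecular framework fraction
#'
#' fMF = (heavy atoms in the Murcko framework) / (heavy atoms), where the
#' framework is what remains after iteratively deleting terminal
#' (degree-one) atoms: ring systems plus their linkers. Only the count is
#' tracked; the framework atoms are never enumerated into a substructure.
#'
#' @inheritParams atom_counts
#' @return Numeric in \[0, 1\]; exactly 0 for acyclic molecules.
#' @export
framework_fraction <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  total <- length(heavy)
  if (total == 0L) return(missing_value("empty_graph", "no heavy atoms"))
  alive <- rep(FALSE, n_atoms(mol)); alive[heavy] <- TRUE
  deg <- function() {
    d <- integer(n_atoms(mol))
    bb <- mol$bonds[alive[mol$bonds$i] & alive[mol$bonds$j], , drop = FALSE]
    if (nrow(bb)) for (k in seq_len(nrow(bb))) {
      d[bb$i[k]] <- d[bb$i[k]] + 1L
      d[bb$j[k]] <- d[bb$j[k]] + 1L
    }
    d
  }
  repeat {
    d <- deg()
    leaves <- which(alive & d <= 1L)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
    if (!any(alive)) break
  }
  sum(alive) / total
}

#' Randic molecular ID descriptors
#'
#' Per-atom weights \eqn{w(v) = 1 + \tfrac12 \sum_{P \ni v}
#' \prod_{(u,t) \in P} (\delta_u \delta_t)^{-1/2}} summed over simple paths
#' with endpoint v. `MID` sums w over all heavy atoms; subset variants
#' restrict to heteroatoms carrying hydrogens (`_h`), carbons (`_C`),
#' nitrogens (`_N`), oxygens (`_O`) and halogens (`_X`). `AMID*` variants
#' divide by the heavy-atom count. Path products are cached incrementally
#' along the depth-first search (each prefix product computed once).
#'
#' @inheritParams atom_counts
#' @param weights optional precomputed weight structure (internal).
#' @return Named list of 12 numbers: `MID`, `AMID`, `MID_h`, `AMID_h`,
#'   `MID_C`, `AMID_C`, `MID_N`, `AMID_N`, `MID_O`, `AMID_O`, `MID_X`,
#'   `AMID_X`.
#' @export
molecular_id <- function(mol, weights = NULL) {
  if (is.null(weights)) weights <- mid_atom_weights(mol)
  w <- weights$weights
  el <- mol$atoms$element
  heavy <- el != "H"
  A <- sum(heavy)
  sel <- list(heavy,
              heavy & !(el %in% c("C", "H")) & mol$atoms$h > 0L,
              el == "C", el == "N", el == "O",
              el %in% c("F", "Cl", "Br", "I"))
  sfxs <- c("", "_h", "_C", "_N", "_O", "_X")
  out <- list()
  for (k in seq_along(sel)) {
    v <- sum(w[sel[[k]]])
    out[[paste0("MID", sfxs[k])]] <- v
    out[[paste0("AMID", sfxs[k])]] <- v / A
  }
  out[c("MID", "AMID", "MID_h", "AMID_h", "MID_C", "AMID_C",
        "MID_N", "AMID_N", "MID_O", "AMID_O", "MID_X", "AMID_X")]
}

#' Atom-bond connectivity indices
#'
#' \eqn{ABC = \sum_{(u,v) \in E} \sqrt{(\delta_u + \delta_v - 2) /
#' (\delta_u \delta_v)}}; the Graovac-Ghorbani variant replaces degrees by
#' the counts \eqn{n_u} of atoms strictly nearer u than v.
#'
#' @inheritParams wiener
#' @param delta optional precomputed [delta_vector()].
#' @return Named list `ABC`, `ABCGG`, or a [missing_value()] with no bonds;
#'   `ABCGG` is missing when the molecule is disconnected.
#' @export
abc_index <- function(mol, dist = NULL, delta = NULL) {
  e <- mol$bonds
  if (!nrow(e)) return(missing_value("empty_graph", "ABC needs at least one bond"))
  d <- if (is.null(delta)) delta_vector(mol) else delta
  abc <- sum(sqrt((d[e$i] + d[e$j] - 2) / (d[e$i] * d[e$j])))
  if (is.null(dist)) dist <- distance_matrix(mol)
  if (is_missing(dist)) return(list(ABC = abc, ABCGG = dist))
  D <- dist$matrix
  gg <- 0
  for (k in seq_len(nrow(e))) {
    u <- e$i[k]; v <- e$j[k]
    nu <- sum(D[, u] < D[, v])
    nv <- sum(D[, v] < D[, u])
    gg <- gg + sqrt((nu + nv - 2) / (nu * nv))
  }
  list(ABC = abc, ABCGG = gg)
}

#' Detour-matrix descriptor suite
#'
#' The 13 [spectral_aggregates()] of the detour matrix (suffix `_Dt`) plus
#' the detour index (half-sum of the matrix entries).
#'
#' @inheritParams atom_counts
#' @param bundle optional precomputed [detour_matrix()] bundle.
#' @return Named list of 14 values, or a [missing_value()] if disconnected.
#' @export
detour_descriptors <- function(mol, bundle = NULL) {
  if (is.null(bundle)) bundle <- detour_matrix(mol)
  if (is_missing(bundle)) return(bundle)
  ag <- spectral_aggregates(bundle)
  names(ag) <- paste0(names(ag), "_Dt")
  c(ag, list(DetourIndex = sum(bundle$matrix) / 2))
}

#' Distance-matrix descriptor suite
#'
#' The 13 [spectral_aggregates()] of the topological distance matrix
#' (suffix `_D`).
#'
#' @inheritParams wiener
#' @return Named list of 13 values, or a [missing_value()] if disconnected.
#' @export
distance_descriptors <- function(mol, dist = NULL) {
  if (is.null(dist)) dist <- distance_matrix(mol)
  if (is_missing(dist)) return(dist)
  ag <- spectral_aggregates(dist)
  names(ag) <- paste0(names(ag), "_D")
  ag
}
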