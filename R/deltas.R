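# Kier-Hall atomic connectivity weights on the hydrogen-suppressed graph.

#' Kier-Hall delta vectors
#'
#' `delta_vector()` is the simple delta: the heavy-atom degree of each atom.
#' `valence_delta_vector()` is the valence delta
#' \eqn{\delta^v = Z^v - h} for second-row atoms and
#' \eqn{\delta^v = (Z^v - h) / (Z - Z^v - 1)} beyond (Z = atomic number,
#' \eqn{Z^v} = valence electrons, h = attached hydrogens).
#'
#' @param mol a hydrogen-suppressed [mol_graph()].
#' @return Numeric vector, one entry per atom.
#' @export
delta_vector <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  heavy <- mol$atoms$element != "H"
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (heavy[j]) d[i] <- d[i] + 1L
      if (heavy[i]) d[j] <- d[j] + 1L
    }
  }
  d
}

#' @rdname delta_vector
#' @export
valence_delta_vector <- function(mol) {
  Z <- mol$atoms$Z
  Zv <- mol$atoms$Zv
  h <- mol$atoms$h
  ifelse(Z > 10, (Zv - h) / (Z - Zv - 1), Zv - h)
}
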