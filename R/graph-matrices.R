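# Atom-pair matrices (adjacency, topological distance, detour) and their
# shared 13-aggregate spectral suite. The detour matrix -- longest simple
# path lengths between all atom pairs, an NP-hard problem in general -- is
# computed exactly by decomposing the molecule at its articulation points
# into biconnected blocks, solving each block by exhaustive depth-first
# search, and merging block results additively along the block-cut tree.
# Molecules are sparse, so blocks stay small and the decomposition makes the
# computation tractable even for large molecules.

#' Square matrix bundle
#'
#' A symmetric atom-pair matrix together with its eigendecomposition and the
#' molecule's edge list (needed by the Randic-like VR aggregates).
#'
#' @param matrix n x n symmetric numeric matrix with zero diagonal.
#' @param kind `"adjacency"`, `"distance"` or `"detour"`.
#' @param edges two-column matrix of bonded atom-index pairs.
#' @return An object of class `square_matrix_bundle` with fields `matrix`,
#'   `kind`, `eigenvalues` (decreasing), `eigenvector` (leading, by absolute
#'   component), `edges`, and `degenerate_top` (flag: top eigenvalue is
#'   numerically degenerate, so eigenvector-based aggregates depend on the
#'   eigensolver's basis choice).
#' @export
square_matrix_bundle <- function(matrix, kind = c("adjacency", "distance", "detour"),
                                 edges = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == ncol(matrix))
  if (any(abs(matrix - t(matrix)) > 1e-9)) stop("matrix must be symmetric")
  if (any(abs(diag(matrix)) > 0)) stop("diagonal must be exactly zero")
  eig <- eigen(matrix, symmetric = TRUE)
  n <- nrow(matrix)
  degen <- n > 1L && abs(eig$values[1] - eig$values[2]) < 1e-9
  structure(list(matrix = matrix, kind = kind,
                 eigenvalues = eig$values,
                 eigenvector = abs(eig$vectors[, 1]),
                 edges = if (is.null(edges)) base::matrix(integer(0), ncol = 2) else as.matrix(edges),
                 degenerate_top = degen),
            class = "square_matrix_bundle")
}

#' @export
print.square_matrix_bundle <- function(x, ...) {
  cat(sprintf("<square_matrix_bundle> kind=%s n=%d\n", x$kind, nrow(x$matrix)))
  invisible(x)
}

mol_edges <- function(mol) {
  if (!nrow(mol$bonds)) return(matrix(integer(0), ncol = 2))
  cbind(mol$bonds$i, mol$bonds$j)
}

#' Adjacency matrix bundle
#'
#' @param mol a [mol_graph()] (hydrogen-suppressed).
#' @return A [square_matrix_bundle()] of kind `"adjacency"`.
#' @export
adjacency_matrix <- function(mol) {
  n <- n_atoms(mol)
  A <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1
  }
  square_matrix_bundle(A, "adjacency", mol_edges(mol))
}

#' Topological distance matrix bundle
#'
#' Entry (i, j) is the shortest-path bond count between atoms i and j
#' (breadth-first search from every atom).
#'
#' @param mol a [mol_graph()]; must be connected.
#' @return A [square_matrix_bundle()] of kind `"distance"`, or a
#'   [missing_value()] with reason `"disconnected"`.
#' @export
distance_matrix <- function(mol) {
  if (!is_connected_mol(mol))
    return(missing_value("disconnected", "distance matrix undefined across fragments"))
  D <- igraph::distances(mol_igraph(mol))
  dimnames(D) <- NULL
  square_matrix_bundle(D, "distance", mol_edges(mol))
}

# ---- articulation-point decomposition --------------------------------------

#' Biconnected decomposition of a molecular graph
#'
#' Standard low-link biconnected decomposition: maximal subgraphs without a
#' cut vertex (blocks), the articulation points, and the block-cut tree that
#' joins them. This is the skeleton of the detour-matrix algorithm.
#'
#' @param mol a connected [mol_graph()].
#' @return An object of class `block_decomposition`: `articulation_points`
#'   (atom indices), `blocks` (list of atom-index vectors), `block_edges`
#'   (list of two-column bond matrices per block), and `block_cut_tree`
#'   (data.frame `block`, `cut_vertex` with one row per incidence).
#' @export
articulation_decompose <- function(mol) {
  stopifnot(is_connected_mol(mol))
  n <- n_atoms(mol)
  if (nrow(mol$bonds) == 0L) {
    return(structure(list(articulation_points = integer(0),
                          blocks = list(seq_len(n)),
                          block_edges = list(matrix(integer(0), ncol = 2)),
                          block_cut_tree = data.frame(block = integer(0),
                                                      cut_vertex = integer(0))),
                     class = "block_decomposition"))
  }
  g <- mol_igraph(mol)
  bc <- igraph::biconnected_components(g)
  aps <- sort(as.integer(names(igraph::articulation_points(g))))
  blocks <- lapply(bc$components, function(v) sort(as.integer(names(v))))
  block_edges <- lapply(bc$component_edges, function(es) {
    em <- igraph::ends(g, es)
    cbind(as.integer(em[, 1]), as.integer(em[, 2]))
  })
  inc <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    cv <- intersect(blocks[[b]], aps)
    if (length(cv)) data.frame(block = b, cut_vertex = cv) else NULL
  }))
  if (is.null(inc)) inc <- data.frame(block = integer(0), cut_vertex = integer(0))
  structure(list(articulation_points = aps, blocks = blocks,
                 block_edges = block_edges, block_cut_tree = inc),
            class = "block_decomposition")
}

#' @export
print.block_decomposition <- function(x, ...) {
  cat(sprintf("<block_decomposition> %d block(s), %d articulation point(s)\n",
              length(x$blocks), length(x$articulation_points)))
  invisible(x)
}

# exhaustive DFS longest simple paths between all pairs inside one block;
# verts: atom indices of the block, edges: two-column matrix of block bonds.
# Returns a |verts| x |verts| matrix in the order of sort(verts).
block_longest_paths <- function(verts, edges) {
  verts <- sort(verts)
  k <- length(verts)
  best <- matrix(0L, k, k)
  if (k <= 1L || nrow(edges) == 0L) return(best)
  li <- match(edges[, 1], verts); lj <- match(edges[, 2], verts)
  adj <- vector("list", k)
  for (t in seq_along(li)) {
    adj[[li[t]]] <- c(adj[[li[t]]], lj[t])
    adj[[lj[t]]] <- c(adj[[lj[t]]], li[t])
  }
  visited <- logical(k)
  dfs <- function(s, u, depth) {
    if (depth > best[s, u]) best[s, u] <<- depth
    visited[u] <<- TRUE
    for (w in adj[[u]]) if (!visited[w]) dfs(s, w, depth + 1L)
    visited[u] <<- FALSE
  }
  for (s in seq_len(k)) dfs(s, s, 0L)
  best
}

#' Detour matrix bundle via articulation-point decomposition
#'
#' Entry (i, j) is the number of bonds on the longest simple path between
#' atoms i and j. Each biconnected block is solved by exhaustive depth-first
#' search; for atoms in different blocks the block-internal longest paths are
#' summed along the unique chain of articulation points joining them, merged
#' outward over the block-cut tree.
#'
#' @param mol a [mol_graph()]; must be connected.
#' @param time_budget optional per-molecule wall-clock budget in seconds; when
#'   exceeded a [missing_value()] with reason `"timeout"` is returned. `Inf`
#'   (default) never times out.
#' @return A [square_matrix_bundle()] of kind `"detour"`, or a
#'   [missing_value()] (`"disconnected"` or `"timeout"`).
#' @export
detour_matrix <- function(mol, time_budget = Inf) {
  if (!is_connected_mol(mol))
    return(missing_value("disconnected", "detour matrix undefined across fragments"))
  t0 <- Sys.time()
  n <- n_atoms(mol)
  dec <- articulation_decompose(mol)
  M <- matrix(0L, n, n)
  block_mats <- vector("list", length(dec$blocks))
  for (b in seq_along(dec$blocks)) {
    if (is.finite(time_budget) &&
        as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_budget)
      return(missing_value("timeout", "detour computation exceeded time budget"))
    block_mats[[b]] <- block_longest_paths(dec$blocks[[b]], dec$block_edges[[b]])
  }
  # merge blocks outward from block 1: each new block is glued to the merged
  # set at exactly one shared (articulation) vertex
  merged <- sort(dec$blocks[[1]])
  vb <- dec$blocks[[1]]
  M[cbind(rep(vb, each = length(vb)), rep(vb, length(vb)))] <-
    as.integer(block_mats[[1]])
  remaining <- setdiff(seq_along(dec$blocks), 1L)
  while (length(remaining)) {
    nxt <- NA_integer_; shared <- NA_integer_
    for (b in remaining) {
      s <- intersect(dec$blocks[[b]], merged)
      if (length(s) >= 1L) { nxt <- b; shared <- s[1]; break }
    }
    if (is.na(nxt)) stop("internal error: block-cut tree not connected")
    vb <- sort(dec$blocks[[nxt]])
    bm <- block_mats[[nxt]]
    M[cbind(rep(vb, each = length(vb)), rep(vb, length(vb)))] <- as.integer(bm)
    a <- shared
    olds <- setdiff(merged, a)
    news <- setdiff(vb, a)
    for (u in olds) for (v in news) {
      M[u, v] <- M[v, u] <- M[u, a] + M[a, v]
    }
    merged <- c(merged, news)
    remaining <- setdiff(remaining, nxt)
  }
  square_matrix_bundle(M, "detour", mol_edges(mol))
}

# ---- numerically stable log-sum-exp ----------------------------------------

#' Numerically stable log-sum-exp
#'
#' Evaluates `log(sum(exp(x)))` as `max(x) + log(sum(exp(x - max(x))))`,
#' which stays finite for inputs whose naive exponentials overflow.
#'
#' @param values non-empty numeric vector.
#' @return `log(sum(exp(values)))` as a finite number whenever the inputs are
#'   finite.
#' @examples
#' lse(c(1000, 1000))  # 1000 + log(2); naive form overflows
#' @export
lse <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("lse() requires a non-empty sequence")
  m <- max(values)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(values - m)))
}

# ---- spectral aggregate suite ----------------------------------------------

.SPECTRAL_NAMES <- c("SpAbs", "SpMax", "SpDiam", "SpAD", "SpMAD", "LogEE",
                     "SM1", "VE1", "VE2", "VE3", "VR1", "VR2", "VR3")

#' Spectral aggregates of a matrix bundle
#'
#' The 13 shared aggregates of an atom-pair matrix: from the spectrum
#' (eigenvalues \eqn{\lambda_1 \ge \dots \ge \lambda_n}) SpAbs =
#' \eqn{\sum|\lambda_i|}, SpMax = \eqn{\lambda_1}, SpDiam = \eqn{\lambda_1 -
#' \lambda_n}, SpAD = \eqn{\sum|\lambda_i - \bar\lambda|}, SpMAD = SpAD/n,
#' LogEE = log-sum-exp of the spectrum (the log of the Estrada-like index,
#' always routed through [lse()]), SM1 = \eqn{\sum\lambda_i} (the trace, 0);
#' and from the leading eigenvector \eqn{c} (absolute components) VE1 =
#' \eqn{\sum|c_i|}, VE2 = VE1/n, VE3 = log(VE1 n / 10), VR1 =
#' \eqn{\sum_{(u,v) \in E}(|c_u||c_v|)^{-1/2}}, VR2 = VR1/n, VR3 =
#' log(VR1 n / 10).
#'
#' @param bundle a [square_matrix_bundle()].
#' @return Named list of 13 numbers; VR entries are a [missing_value()]
#'   (`"divide_by_zero"`) when a leading-eigenvector component vanishes on a
#'   bonded atom.
#' @export
spectral_aggregates <- function(bundle) {
  stopifnot(inherits(bundle, "square_matrix_bundle"))
  lam <- bundle$eigenvalues
  n <- length(lam)
  if (n == 0L) return(missing_value("empty_graph", "no atoms"))
  c_abs <- bundle$eigenvector
  ve1 <- sum(c_abs)
  out <- list(
    SpAbs = sum(abs(lam)),
    SpMax = lam[1],
    SpDiam = lam[1] - lam[n],
    SpAD = sum(abs(lam - mean(lam))),
    SpMAD = sum(abs(lam - mean(lam))) / n,
    LogEE = lse(lam),
    SM1 = sum(lam),
    VE1 = ve1,
    VE2 = ve1 / n,
    VE3 = log(ve1 * n / 10)
  )
  E <- bundle$edges
  if (nrow(E) == 0L) {
    vr1 <- 0
  } else {
    cu <- c_abs[E[, 1]]; cv <- c_abs[E[, 2]]
    if (any(cu * cv < 1e-24)) {
      mv <- missing_value("divide_by_zero",
                          "zero leading-eigenvector component on a bonded atom")
      out$VR1 <- mv; out$VR2 <- mv; out$VR3 <- mv
      return(out[.SPECTRAL_NAMES])
    }
    vr1 <- sum((cu * cv)^(-0.5))
  }
  out$VR1 <- vr1
  out$VR2 <- vr1 / n
  out$VR3 <- log(vr1 * n / 10)
  out[.SPECTRAL_NAMES]
}
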