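# Synthetic molecular-graph generators and independent brute-force oracles.
# The generators build deterministic, connected, simple graphs (carbon-only
# by default) for property-based testing; the oracles re-derive quantities by
# naive exhaustive enumeration and deliberately share no code with the
# optimized algorithms they validate.

#' Graph recipe
#'
#' @param kind one of `"path"`, `"cycle"`, `"random_tree"`,
#'   `"random_connected"`, `"ring_with_tail"`, `"two_rings_bridged"`.
#' @param n atom count (>= 1; ring kinds need enough atoms for a 3-ring).
#' @param seed RNG seed; identical recipe + seed gives an identical graph.
#' @param element_palette atomic symbols to draw atoms from (default all
#'   carbon).
#' @return A `graph_recipe` for [generate_graph()].
#' @export
graph_recipe <- function(kind = c("path", "cycle", "random_tree",
                                  "random_connected", "ring_with_tail",
                                  "two_rings_bridged"),
                         n, seed = 1L, element_palette = "C") {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  structure(list(kind = kind, n = n, seed = as.integer(seed),
                 element_palette = element_palette),
            class = "graph_recipe")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic molecular graph
#'
#' @param recipe a [graph_recipe()].
#' @return A connected, simple [mol_graph()].
#' @examples
#' generate_graph(graph_recipe("cycle", 6))  # cyclohexane skeleton
#' @export
generate_graph <- function(recipe) {
  stopifnot(inherits(recipe, "graph_recipe"))
  n <- recipe$n
  edges <- with_seed(recipe$seed, switch(
    recipe$kind,
    path = if (n > 1L) cbind(1:(n - 1), 2:n) else NULL,
    cycle = {
      if (n < 3L) stop("cycle needs n >= 3")
      cbind(1:n, c(2:n, 1L))
    },
    random_tree = random_tree_edges(n),
    random_connected = {
      e <- random_tree_edges(n)
      extra <- max(0L, floor(n / 3))
      all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      have <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      cand <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), , drop = FALSE]
      if (nrow(cand) && extra > 0L) {
        take <- sample(nrow(cand), min(extra, nrow(cand)))
        e <- rbind(e, cand[take, , drop = FALSE])
      }
      e
    },
    ring_with_tail = {
      if (n < 4L) stop("ring_with_tail needs n >= 4")
      r <- max(3L, ceiling(n / 2))
      ring <- cbind(1:r, c(2:r, 1L))
      tail <- if (n > r) cbind(r:(n - 1), (r + 1):n) else NULL
      rbind(ring, tail)
    },
    two_rings_bridged = {
      # triangle on 1..3, path 3..(n-2), triangle on (n-2)..n
      if (n < 7L) stop("two_rings_bridged needs n >= 7")
      ring1 <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
      s <- n - 2L
      bridge <- cbind(3:(s - 1), 4:s)
      ring2 <- rbind(c(s, s + 1L), c(s + 1L, n), c(n, s))
      rbind(ring1, bridge, ring2)
    }
  ))
  elements <- with_seed(recipe$seed + 1L,
                        sample(recipe$element_palette, n, replace = TRUE))
  mol_graph(elements, edges, name = paste0(recipe$kind, n, "s", recipe$seed))
}

random_tree_edges <- function(n) {
  if (n == 1L) return(NULL)
  cbind(vapply(2:n, function(v) sample.int(v - 1L, 1L), 0L), 2:n)
}

#' Relabel atoms by a permutation
#'
#' Utility for permutation-invariance testing: atom k of the result is atom
#' `perm[k]`... more precisely, atom v moves to position `perm[v]`.
#'
#' @param mol a [mol_graph()].
#' @param perm permutation of `1:n_atoms`.
#' @return The relabelled (isomorphic) `mol_graph`.
#' @export
permute_graph <- function(mol, perm) {
  n <- n_atoms(mol)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- order(perm)
  out <- mol
  out$atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out$bonds$i <- perm[mol$bonds$i]
  out$bonds$j <- perm[mol$bonds$j]
  out
}

# ---- oracles ----------------------------------------------------------------

#' Exhaustive longest-simple-path oracle
#'
#' Ground truth for [detour_matrix()]: a naive depth-first enumeration of
#' every simple path in the whole graph (no decomposition), recording the
#' maximal edge count between every pair. Exponential; refuses n > 14.
#'
#' @param mol a connected [mol_graph()] with at most 14 atoms.
#' @return Integer matrix of longest-path lengths.
#' @export
oracle_longest_paths <- function(mol) {
  n <- n_atoms(mol)
  if (n > 14L) stop("oracle_longest_paths is exponential; refusing n > 14")
  adj <- adjacency_list(mol)
  best <- matrix(0L, n, n)
  visited <- logical(n)
  dfs <- function(s, u, depth) {
    if (depth > best[s, u]) best[s, u] <<- depth
    visited[u] <<- TRUE
    for (w in adj[[u]]) if (!visited[w]) dfs(s, w, depth + 1L)
    visited[u] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, s, 0L)
  best
}

#' Exhaustive subgraph-classification oracle
#'
#' Ground truth for the chi subgraph enumeration: every m-subset of bonds is
#' tested for connectedness and classified by shape from first principles
#' (cycle rank, degree sequence, diameter). Refuses n > 10.
#'
#' @param mol a [mol_graph()] with at most 10 atoms.
#' @param kind shape class (`"path"`, `"chain"`, `"cluster"`,
#'   `"path_cluster"`).
#' @param order subgraph bond count m >= 0.
#' @return List of sorted atom-index vectors, one per subgraph of the class.
#' @export
oracle_subgraphs <- function(mol, kind, order) {
  if (n_atoms(mol) > 10L) stop("oracle_subgraphs is exponential; refusing n > 10")
  kind <- match.arg(kind, c("path", "chain", "cluster", "path_cluster"))
  order <- as.integer(order)
  if (order == 0L) {
    if (kind != "path") return(list())
    return(lapply(seq_len(n_atoms(mol)), identity))
  }
  ne <- nrow(mol$bonds)
  if (ne < order) return(list())
  combos <- utils::combn(ne, order, simplify = FALSE)
  out <- list()
  for (sub in combos) {
    vi <- mol$bonds$i[sub]; vj <- mol$bonds$j[sub]
    verts <- sort(unique(c(vi, vj)))
    # connectivity by label propagation over the chosen bonds
    lab <- seq_along(verts)
    names(lab) <- verts
    repeat {
      changed <- FALSE
      for (t in seq_along(sub)) {
        a <- as.character(vi[t]); b <- as.character(vj[t])
        m <- min(lab[a], lab[b])
        if (lab[a] != m || lab[b] != m) { lab[a] <- m; lab[b] <- m; changed <- TRUE }
      }
      if (!changed) break
    }
    if (length(unique(lab)) != 1L) next
    nv <- length(verts)
    deg <- integer(nv); names(deg) <- verts
    for (t in seq_along(sub)) {
      deg[as.character(vi[t])] <- deg[as.character(vi[t])] + 1L
      deg[as.character(vj[t])] <- deg[as.character(vj[t])] + 1L
    }
    k <- if (order >= nv) "chain"
         else if (max(deg) <= 2L) "path"
         else {
      # any 3-edge path inside? equivalently an edge whose two ends both have
      # another neighbour in the subgraph
      pc <- FALSE
      for (t in seq_along(sub)) {
        if (deg[as.character(vi[t])] >= 2L && deg[as.character(vj[t])] >= 2L) {
          pc <- TRUE; break
        }
      }
      if (pc) "path_cluster" else "cluster"
    }
    if (k == kind) out[[length(out) + 1L]] <- verts
  }
  out
}

#' Exhaustive simple-path oracle
#'
#' Ground truth for the molecular-ID path weights: every simple path with at
#' least one bond, enumerated exactly once up to direction reversal (the
#' lower endpoint index comes first). Refuses n > 10.
#'
#' @param mol a [mol_graph()] with at most 10 atoms.
#' @return List of atom-index vectors (paths in vertex order).
#' @export
oracle_simple_paths <- function(mol) {
  n <- n_atoms(mol)
  if (n > 10L) stop("oracle_simple_paths is exponential; refusing n > 10")
  adj <- adjacency_list(mol)
  out <- list()
  path <- integer(0)
  visited <- logical(n)
  dfs <- function(u) {
    path <<- c(path, u)
    visited[u] <<- TRUE
    if (length(path) >= 2L && path[1] < u)
      out[[length(out) + 1L]] <<- path
    for (w in adj[[u]]) if (!visited[w]) dfs(w)
    visited[u] <<- FALSE
    path <<- path[-length(path)]
  }
  for (s in seq_len(n)) dfs(s)
  out
}
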