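test_that("distance matrix equals BFS shortest paths and Floyd-Warshall oracle", {
  p3 <- chain(3)
  expect_equal(distance_matrix(p3)$matrix,
               matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3))
  expect_equal(distance_matrix(mol_graph("C"))$matrix, matrix(0, 1, 1))

  # Floyd-Warshall oracle on cyclohexane and random graphs
  fw <- function(mol) {
    n <- nrow(mol$atoms)
    D <- matrix(Inf, n, n); diag(D) <- 0
    for (k in seq_len(nrow(mol$bonds))) {
      D[mol$bonds$i[k], mol$bonds$j[k]] <- 1
      D[mol$bonds$j[k], mol$bonds$i[k]] <- 1
    }
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
  }
  for (s in 1:5) {
    m <- generate_graph(graph_recipe("random_connected", 8, seed = s))
    expect_equal(distance_matrix(m)$matrix, fw(m))
  }
  c6 <- distance_matrix(cyclo(6))$matrix
  expect_true(all(c6[upper.tri(c6)] %in% 1:3))
})

test_that("distance and detour matrices are missing on disconnected molecules", {
  dd <- mol_graph(rep("C", 4), rbind(c(1, 2), c(3, 4)))
  expect_missing_reason(distance_matrix(dd), "disconnected")
  expect_missing_reason(detour_matrix(dd), "disconnected")
})

test_that("biconnected decomposition matches the textbook definition", {
  # tree: every edge its own block, every internal vertex an articulation point
  tr <- generate_graph(graph_recipe("random_tree", 8, seed = 3))
  dec <- articulation_decompose(tr)
  expect_length(dec$blocks, nrow(tr$bonds))
  internal <- which(delta_vector(tr) >= 2)
  expect_setequal(dec$articulation_points, internal)

  # single ring: one block, no articulation points
  dec6 <- articulation_decompose(cyclo(6))
  expect_length(dec6$blocks, 1)
  expect_length(dec6$articulation_points, 0)

  # ring with tail: cut vertex at the junction, ring block + tail edges
  rt <- skeleton(6, rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5), c(5, 6)))
  dec_rt <- articulation_decompose(rt)
  expect_true(3 %in% dec_rt$articulation_points)
  sizes <- sort(vapply(dec_rt$blocks, length, 0L))
  expect_equal(sizes, c(2L, 2L, 2L, 3L))
  # removing an articulation point indeed disconnects the graph
  for (a in dec_rt$articulation_points) {
    rest <- setdiff(seq_len(6), a)
    keep <- rt$bonds$i != a & rt$bonds$j != a
    g <- igraph::graph_from_data_frame(rt$bonds[keep, 1:2], directed = FALSE,
                                       vertices = data.frame(name = rest))
    expect_false(igraph::is_connected(g))
  }
})

test_that("detour matrix equals the exhaustive whole-graph DFS oracle", {
  # spot values: cyclopentane and cyclohexane detour indices
  d5 <- detour_matrix(cyclo(5))$matrix
  expect_equal(sum(d5) / 2, 35)
  expect_true(all(d5[cbind(1:5, c(2:5, 1))] == 4))
  d6 <- detour_matrix(cyclo(6))$matrix
  expect_equal(sum(d6) / 2, 63)

  withr::with_seed(11, {
    for (rep in 1:20) {
      m <- generate_graph(graph_recipe("random_connected", sample(4:12, 1),
                                       seed = 1000 + rep))
      expect_identical(detour_matrix(m)$matrix, oracle_longest_paths(m))
    }
  })
})

test_that("detour equals distance on trees and dominates distance everywhere", {
  withr::with_seed(12, {
    for (rep in 1:15) {
      tr <- generate_graph(graph_recipe("random_tree", sample(2:20, 1),
                                        seed = 2000 + rep))
      expect_equal(detour_matrix(tr)$matrix, distance_matrix(tr)$matrix)
    }
    for (rep in 1:10) {
      m <- generate_graph(graph_recipe("random_connected", sample(4:12, 1),
                                       seed = 3000 + rep))
      expect_true(all(detour_matrix(m)$matrix >= distance_matrix(m)$matrix))
    }
  })
})

test_that("optional detour time budget returns a typed timeout", {
  m <- generate_graph(graph_recipe("random_connected", 12, seed = 5))
  expect_missing_reason(detour_matrix(m, time_budget = 0), "timeout")
})

test_that("lse matches the naive form in the safe range and is finite at overflow", {
  expect_equal(lse(0), 0)
  expect_equal(lse(c(1000, 1000)), 1000 + log(2))
  expect_true(is.finite(lse(c(1000, 1000))))
  expect_true(is.infinite(log(sum(exp(c(1000, 1000))))))  # naive overflows
  withr::with_seed(7, {
    for (rep in 1:20) {
      x <- stats::runif(10, -5, 5)
      expect_equal(lse(x), log(sum(exp(x))), tolerance = 1e-12)
    }
  })
  expect_error(lse(numeric(0)), "non-empty")
})

test_that("spectral aggregates match closed-form spectra", {
  # P2 adjacency: eigenvalues +/- 1
  p2 <- adjacency_matrix(chain(2))
  ag <- spectral_aggregates(p2)
  expect_equal(ag$SpMax, 1)
  expect_equal(ag$SpDiam, 2)
  expect_equal(ag$SM1, 0, tolerance = 1e-12)
  expect_equal(ag$SpAbs, 2)

  # cyclohexane adjacency: circulant spectrum 2cos(2*pi*k/6), max 2
  ag6 <- spectral_aggregates(adjacency_matrix(cyclo(6)))
  expect_equal(ag6$SpMax, 2)
  expect_equal(sort(adjacency_matrix(cyclo(6))$eigenvalues),
               sort(2 * cos(2 * pi * (0:5) / 6)), tolerance = 1e-9)

  # single atom
  ag1 <- spectral_aggregates(adjacency_matrix(mol_graph("C")))
  expect_equal(ag1$SpAbs, 0)
  expect_equal(ag1$LogEE, 0)
  expect_equal(ag1$SM1, 0)
})

test_that("trace aggregate SM1 is zero for all three matrix kinds", {
  m <- generate_graph(graph_recipe("ring_with_tail", 9, seed = 2))
  for (bundle in list(adjacency_matrix(m), distance_matrix(m), detour_matrix(m)))
    expect_equal(spectral_aggregates(bundle)$SM1, 0, tolerance = 1e-9)
})

test_that("LogEE stays finite for spectra of magnitude 1e4", {
  # scaled distance-like matrix with huge eigenvalues; naive exp overflows
  m <- generate_graph(graph_recipe("path", 12, seed = 1))
  big <- distance_matrix(m)$matrix * 1e3
  bundle <- square_matrix_bundle(big, "distance", cbind(1:11, 2:12))
  expect_gt(max(abs(bundle$eigenvalues)), 1e3)
  ag <- spectral_aggregates(bundle)
  expect_true(is.finite(ag$LogEE))
  expect_equal(ag$LogEE, max(bundle$eigenvalues) +
                 log(sum(exp(bundle$eigenvalues - max(bundle$eigenvalues)))))
})

test_that("all aggregates are invariant under vertex permutation", {
  m <- generate_graph(graph_recipe("two_rings_bridged", 9, seed = 4))
  base <- spectral_aggregates(distance_matrix(m))
  withr::with_seed(21, {
    for (rep in 1:5) {
      pm <- permute_graph(m, sample(9))
      agp <- spectral_aggregates(distance_matrix(pm))
      for (nm in names(base)) expect_equal(agp[[nm]], base[[nm]], tolerance = 1e-9)
    }
  })
})
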