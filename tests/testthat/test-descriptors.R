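test_that("atom counts tally elements, hydrogens and halogens", {
  eth <- atom_counts(smiles_mol("CCO"))
  expect_equal(eth$nAtom, 9)        # C2H6O
  expect_equal(eth$nHeavyAtom, 3)
  expect_equal(eth$nC, 2)
  expect_equal(eth$nO, 1)
  expect_equal(eth$nH, 6)

  benz <- atom_counts(smiles_mol("c1ccccc1"))
  expect_equal(benz$nC, 6)
  expect_equal(benz$nH, 6)
  expect_equal(benz$nX, 0)

  clb <- atom_counts(smiles_mol("Clc1ccccc1"))
  expect_equal(clb$nCl, 1)
  expect_equal(clb$nX, 1)
})

test_that("spiro and bridgehead atoms are counted from SSSR ring sharing", {
  # spiro[4.4]nonane: two 5-rings sharing one atom
  spiro <- skeleton(9, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1),
                             c(5, 6), c(6, 7), c(7, 8), c(8, 9), c(9, 5)))
  ac <- atom_counts(spiro)
  expect_equal(ac$nSpiro, 1)
  expect_equal(ac$nBridgehead, 0)

  # norbornane: bicyclo[2.2.1]heptane, two bridgehead atoms
  nor <- skeleton(7, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                           c(6, 1), c(1, 7), c(7, 4)))
  acn <- atom_counts(nor)
  expect_equal(acn$nBridgehead, 2)
  expect_equal(acn$nSpiro, 0)

  # fused (naphthalene): neither spiro nor bridgehead
  acf <- atom_counts(smiles_mol("c1ccc2ccccc2c1"))
  expect_equal(acf$nSpiro, 0)
  expect_equal(acf$nBridgehead, 0)
})

test_that("Zagreb indices are exact on hand-enumerated graphs", {
  z <- zagreb_indices(methylbutane())  # degrees (1,3,2,1,1)
  expect_equal(z$Zagreb1, 16)
  expect_equal(z$Zagreb2, 14)
  expect_identical(z$mZagreb2, 4 / 3)  # 1/3+1/6+1/2+1/3, exact rational sum
  expect_equal(z$mZagreb1, 1 + 1 / 9 + 1 / 4 + 1 + 1)

  z1 <- zagreb_indices(mol_graph("C"))
  expect_equal(z1$Zagreb1, 0)
  expect_equal(z1$Zagreb2, 0)
})

test_that("Wiener indices match the brute-force all-pairs oracle", {
  w <- wiener(methylbutane())
  expect_equal(w$WPath, 18)
  expect_equal(w$WPol, 2)
  expect_equal(wiener(cyclo(6))$WPath, 27)
  w2 <- wiener(chain(2))
  expect_equal(w2$WPath, 1)
  expect_equal(w2$WPol, 0)
})

test_that("Balaban J reproduces closed-form values", {
  expect_equal(balaban_j(cyclo(6)), 2.0)
  # n-butane: s = (6,4,4,6), M = 3, mu = 0
  expect_equal(balaban_j(chain(4)),
               3 * (2 / sqrt(24) + 1 / 4), tolerance = 1e-9)
  expect_equal(round(balaban_j(chain(4)), 4), 1.9747)
  expect_equal(balaban_j(chain(2)), 1.0)
  expect_missing_reason(balaban_j(mol_graph("C")), "empty_graph")
})

test_that("chi spot values match hand-derived sums", {
  expect_equal(chi(chain(3), "path", 1, "simple"), sqrt(2))
  expect_equal(chi(isobutane(), "path", 0, "simple"), 3 + 1 / sqrt(3))
  # acyclic molecules have no chain subgraphs at any order
  for (m in 3:7) expect_equal(chi(methylbutane(), "chain", m, "simple"), 0)
  # averaged variant with no subgraphs is a typed missing
  expect_missing_reason(chi(chain(2), "path", 5, "averaged_simple"),
                        "divide_by_zero")
  # valence variant differs from simple when heteroatoms present
  eth <- smiles_mol("CCO")
  expect_false(isTRUE(all.equal(chi(eth, "path", 1, "simple"),
                                chi(eth, "path", 1, "valence"))))
})

test_that("chi DFS enumeration equals the exhaustive subset oracle", {
  withr::with_seed(31, {
    for (rep in 1:12) {
      m <- generate_graph(graph_recipe("random_connected", sample(4:10, 1),
                                       seed = 4000 + rep))
      for (ord in 0:7) {
        subs <- topodesc:::classified_edge_subgraphs(m, ord)
        for (kind in c("path", "chain", "cluster", "path_cluster")) {
          mine <- vertex_keys(lapply(Filter(function(s) s$kind == kind, subs),
                                     function(s) s$vertices))
          orc <- vertex_keys(oracle_subgraphs(m, kind, ord))
          expect_identical(mine, orc)
        }
      }
    }
  })
})

test_that("kappa shape indices follow the Kier formulas", {
  for (A in c(3, 5, 8)) expect_equal(kappa_shape(chain(A))$Kier1, A)
  expect_equal(kappa_shape(chain(5))$Kier2, 4)  # (4*9)/9
  expect_equal(kappa_shape(cyclo(6))$Kier1, 6 * 25 / 36)
  # parity rule for Kier3
  expect_equal(kappa_shape(chain(5))$Kier3, 4 * 4 / 4)   # odd A: (A-1)(A-3)^2/P3^2
  expect_equal(kappa_shape(chain(6))$Kier3, 3 * 16 / 9)  # even A: (A-3)(A-2)^2/P3^2
  expect_missing_reason(kappa_shape(chain(2))$Kier1, "empty_graph")
  expect_missing_reason(kappa_shape(chain(3))$Kier2, "empty_graph")
})

test_that("eccentric connectivity sums degree times eccentricity", {
  expect_equal(eccentric_connectivity(cyclo(6)), 36)
  expect_equal(eccentric_connectivity(methylbutane()), 19)
  expect_equal(eccentric_connectivity(chain(2)), 2)
})

test_that("ring counts report SSSR ring sizes over an extensible range", {
  benz <- ring_counts(smiles_mol("c1ccccc1"))
  expect_equal(benz$nRing6, 1)
  expect_equal(sum(unlist(benz)), 1)
  expect_equal(ring_counts(smiles_mol("c1ccc2ccccc2c1"))$nRing6, 2)
  expect_true(all(unlist(ring_counts(chain(6))) == 0))
  # macrocycle visible only with an extended range
  c14 <- cyclo(14)
  expect_equal(sum(unlist(ring_counts(c14, sizes = 3:12))), 0)
  expect_equal(ring_counts(c14, sizes = 3:16)$nRing14, 1)
})

test_that("framework fraction is the Murcko pruning ratio", {
  expect_equal(framework_fraction(smiles_mol("c1ccccc1")), 1.0)
  expect_equal(framework_fraction(chain(6)), 0.0)
  expect_equal(framework_fraction(smiles_mol("Cc1ccccc1")), 6 / 7)
  expect_equal(framework_fraction(generate_graph(graph_recipe("ring_with_tail", 8, seed = 1))),
               0.5)
})

test_that("molecular ID matches the uncached exhaustive-path oracle", {
  expect_equal(molecular_id(mol_graph("C"))$MID, 1)
  expect_equal(molecular_id(chain(2))$MID, 3)

  uncached_mid <- function(m) {
    d <- delta_vector(m)
    S <- numeric(nrow(m$atoms))
    for (p in oracle_simple_paths(m)) {
      wgt <- prod(vapply(seq_len(length(p) - 1),
                         function(t) (d[p[t]] * d[p[t + 1]])^(-0.5), 0))
      S[p[1]] <- S[p[1]] + wgt
      S[p[length(p)]] <- S[p[length(p)]] + wgt
    }
    sum(1 + S / 2)
  }
  withr::with_seed(41, {
    for (rep in 1:10) {
      m <- generate_graph(graph_recipe("random_connected", sample(3:9, 1),
                                       seed = 5000 + rep))
      expect_equal(molecular_id(m)$MID, uncached_mid(m), tolerance = 1e-12)
    }
  })
})

test_that("molecular ID subsets partition by atom type", {
  eth <- smiles_mol("CCO")
  mid <- molecular_id(eth)
  expect_length(mid, 12)
  expect_equal(mid$AMID, mid$MID / 3)
  expect_equal(mid$MID_N, 0)
  expect_gt(mid$MID_O, 0)
  expect_equal(mid$MID_h, mid$MID_O)  # the O-H oxygen is the only H-bearing heteroatom
  expect_equal(mid$MID_C + mid$MID_O, mid$MID)
})

test_that("ABC indices follow the degree and Graovac-Ghorbani formulas", {
  expect_equal(abc_index(cyclo(6))$ABC, 6 * sqrt(2 / 4))
  expect_equal(abc_index(chain(2))$ABC, 0)
  expect_equal(abc_index(chain(3))$ABC, 2 * sqrt(1 / 2))
  expect_missing_reason(abc_index(mol_graph("C")), "empty_graph")
  # ABCGG on even cycle: nu = nv = n/2 (opposite vertex equidistant)
  gg <- abc_index(cyclo(6))$ABCGG
  expect_equal(gg, 6 * sqrt((3 + 3 - 2) / 9))
})

test_that("detour suite equals distance suite on trees and adds the detour index", {
  tr <- generate_graph(graph_recipe("random_tree", 9, seed = 6))
  dd <- detour_descriptors(tr)
  ds <- distance_descriptors(tr)
  for (nm in names(ds))
    expect_equal(dd[[sub("_D$", "_Dt", nm)]], ds[[nm]], tolerance = 1e-9)
  expect_equal(detour_descriptors(cyclo(5))$DetourIndex, 35)
  expect_equal(detour_descriptors(cyclo(6))$DetourIndex, 63)
  expect_length(dd, 14)
})

test_that("every registered descriptor is invariant under atom permutation", {
  calc <- full_calculator()
  mols <- list(smiles_mol("CC(C)Cc1ccccc1"),
               generate_graph(graph_recipe("two_rings_bridged", 9, seed = 8)))
  withr::with_seed(51, {
    for (m in mols) {
      base <- as_mapping(fill_missing(calculate(calc, m)))
      for (rep in 1:5) {
        pm <- permute_graph(m, sample(nrow(m$atoms)))
        got <- as_mapping(fill_missing(calculate(calc, pm)))
        for (nm in names(base)) {
          if (is.nan(base[[nm]])) expect_true(is.nan(got[[nm]]))
          else expect_equal(got[[nm]], base[[nm]], tolerance = 1e-9,
                            label = nm)
        }
      }
    }
  })
})
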