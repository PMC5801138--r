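test_that("registration preserves order, rejects collisions, expands presets", {
  calc <- calculator("WienerIndex")
  expect_equal(names(calc), c("WPath", "WPol"))
  expect_error(register(calc, preset("WienerIndex")[[1]]), "already registered")

  chi_calc <- calculator("Chi")
  expect_length(chi_calc, 56)

  expect_error(preset("NoSuchFamily"), "unknown descriptor family")

  # registration order equals result order
  calc2 <- calculator("ZagrebIndex", "WienerIndex")
  rs <- calculate(calc2, methylbutane())
  expect_identical(names(as_mapping(rs)),
                   c("Zagreb1", "Zagreb2", "mZagreb1", "mZagreb2", "WPath", "WPol"))
})

test_that("preset parameter overrides extend ranges without source changes", {
  expect_length(preset("RingCount"), 10)           # sizes 3..12
  expect_length(preset("RingCount", max_n = 16), 14)
  expect_error(preset("RingCount", max_n = 8), ">= 12")
  expect_length(preset("KappaShapeIndex"), 3)
})

test_that("calculate evaluates every descriptor once with shared caching", {
  calc <- calculator("WienerIndex", "BalabanJ", "EccentricConnectivityIndex",
                     "DistanceMatrix")
  m <- methylbutane()
  rs <- calculate(calc, m)
  expect_length(rs, length(calc))
  mm <- as_mapping(rs)
  expect_equal(mm$WPath, 18)
  expect_equal(mm$ECIndex, 19)
  # caching transparency: identical values with the cache disabled
  rs_nc <- calculate(calc, m, cache = FALSE)
  expect_identical(as_mapping(rs_nc), mm)
})

test_that("failures are contained as typed missing values, never raised", {
  calc <- calculator("BalabanJ", "ZagrebIndex")
  dd <- mol_graph(rep("C", 4), rbind(c(1, 2), c(3, 4)), name = "two-frags")
  rs <- calculate(calc, dd)
  mm <- as_mapping(rs)
  expect_missing_reason(mm$BalabanJ, "disconnected")
  # additive descriptors still computed across fragments
  expect_equal(mm$Zagreb1, 4)

  # single atom with Wiener preset: defined, zero
  rs1 <- as_mapping(calculate(calculator("WienerIndex"), mol_graph("C")))
  expect_equal(rs1$WPath, 0)
  expect_equal(rs1$WPol, 0)

  # parse failure propagates to every entry
  bad <- read_molecules("C1CC(xyz bad", format = "smiles")[[1]]
  rsb <- calculate(calc, bad)
  expect_true(all(vapply(as_mapping(rsb), is_missing, TRUE)))
  expect_true(all(vapply(as_mapping(rsb), function(v) v$reason, "") == "parse_failure"))

  # strict mode raises instead
  expect_error(calculate(calc, dd, strict = TRUE), "disconnected")
})

test_that("fill_missing, drop_missing and as_mapping follow result semantics", {
  calc <- calculator("BalabanJ", "ZagrebIndex")
  dd <- mol_graph(rep("C", 4), rbind(c(1, 2), c(3, 4)))
  rs <- calculate(calc, dd)
  filled <- fill_missing(rs)
  expect_true(is.nan(as_mapping(filled)$BalabanJ))
  expect_length(filled, 5)
  filled9 <- fill_missing(rs, -999)
  expect_equal(as_mapping(filled9)$BalabanJ, -999)
  dropped <- drop_missing(rs)
  expect_length(dropped, 4)
  expect_false("BalabanJ" %in% names(as_mapping(dropped)))
  # no missing: drop is the identity
  ok <- calculate(calculator("ZagrebIndex"), methylbutane())
  expect_identical(as_mapping(drop_missing(ok)), as_mapping(ok))
})

test_that("parallel map preserves order and matches the serial run", {
  calc <- calculator("WienerIndex", "ZagrebIndex", "Chi")
  mols <- c(read_molecules(c("CCO a", "CC(C)C b", "c1ccccc1 c"), format = "smiles"),
            list(generate_graph(graph_recipe("ring_with_tail", 8, seed = 1))))
  serial <- map_parallel(calc, mols, processes = 1)
  for (p in c(2, 3, 4)) {
    par <- map_parallel(calc, mols, processes = p)
    expect_identical(lapply(par, as_mapping), lapply(serial, as_mapping))
    expect_identical(vapply(par, function(r) r$molecule_name, ""),
                     vapply(serial, function(r) r$molecule_name, ""))
  }
  expect_identical(map_parallel(calc, list(), processes = 2), list())
})

test_that("one bad record gives one all-missing row, others unaffected", {
  calc <- calculator("ZagrebIndex")
  mols <- read_molecules(c("CCO a", "C1CC(xyz bad", "CC c"), format = "smiles")
  res <- map_parallel(calc, mols, processes = 2)
  expect_false(any(vapply(as_mapping(res[[1]]), is_missing, TRUE)))
  expect_true(all(vapply(as_mapping(res[[2]]), is_missing, TRUE)))
  expect_false(any(vapply(as_mapping(res[[3]]), is_missing, TRUE)))
})

test_that("descriptor arithmetic composes values and propagates missing", {
  z <- preset("ZagrebIndex")
  m <- methylbutane()
  prod_term <- z[[1]] * z[[2]]
  calc <- register(calculator("ZagrebIndex"), prod_term)
  mm <- as_mapping(calculate(calc, m))
  expect_equal(mm[[prod_term$name]], 224)  # 16 * 14

  # d - d == 0 on every molecule
  diff_term <- z[[1]] - z[[1]]
  for (mol in list(m, cyclo(6), smiles_mol("CCO"))) {
    v <- as_mapping(calculate(register(calculator(), diff_term), mol))[[1]]
    expect_equal(v, 0)
  }

  # constant operands and unary negation
  scaled <- z[[1]] * 2
  neg <- -z[[1]]
  cc <- register(register(calculator(), scaled), neg)
  mm2 <- as_mapping(calculate(cc, m))
  expect_equal(mm2[[scaled$name]], 32)
  expect_equal(mm2[[neg$name]], -16)

  # missing operand -> dependency_failure
  bj <- preset("BalabanJ")[[1]]
  comp <- bj + z[[1]]
  dd <- mol_graph(rep("C", 4), rbind(c(1, 2), c(3, 4)))
  v <- as_mapping(calculate(register(calculator(), comp), dd))[[1]]
  expect_missing_reason(v, "dependency_failure")

  # division by zero at evaluation
  w <- preset("WienerIndex")
  ratio <- z[[1]] / w[[2]]  # WPol = 0 on small molecules
  v0 <- as_mapping(calculate(register(calculator(), ratio), chain(3)))[[1]]
  expect_missing_reason(v0, "divide_by_zero")
})

test_that("result metadata records the aromaticity model", {
  rs <- calculate(calculator("ZagrebIndex"), smiles_mol("c1ccccc1"))
  expect_identical(attr(rs, "metadata")$aromaticity_model, "sssr-huckel")
})
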