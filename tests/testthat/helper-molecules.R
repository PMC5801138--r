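# Shared fixture molecules, built in code. Skeleton graphs are carbon-only
# mol_graph objects; named molecules come from SMILES literals.

skeleton <- function(n, edges, name = "") {
  mol_graph(rep("C", n), edges, name = name)
}

# 2-methylbutane skeleton: degrees (1,3,2,1,1)
methylbutane <- function() skeleton(5, rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5)),
                                    name = "2-methylbutane")

isobutane <- function() skeleton(4, rbind(c(1, 2), c(2, 3), c(2, 4)),
                                 name = "isobutane")

cyclo <- function(n) generate_graph(graph_recipe("cycle", n))
chain <- function(n) generate_graph(graph_recipe("path", n))

smiles_mol <- function(smi) read_molecules(smi, format = "smiles")[[1]]

# sorted "v1,v2,..." keys for subgraph-set comparison
vertex_keys <- function(lst) sort(vapply(lst, function(v) paste(v, collapse = ","), ""))

expect_missing_reason <- function(x, reason) {
  expect_true(is_missing(x))
  expect_identical(x$reason, reason)
}
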