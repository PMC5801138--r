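---
title: "Topological descriptors in topodesc: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological descriptors in topodesc: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topodesc)
```

## The problem

Quantitative structure–property relationship (QSPR) modelling turns a
molecule's symbolic structure into a vector of numbers — molecular
descriptors — and regresses a property of interest on them. This package
computes 2D *topological* descriptors: quantities defined purely on the
hydrogen-suppressed molecular graph (atoms as vertices, bonds as edges),
independent of any 3D conformation. Because they are graph invariants, every
descriptor here is unchanged by atom relabelling and trivially invariant to
rotation and translation, two properties the test suite enforces for every
descriptor rather than assuming.

## The molecular graph and preprocessing

A `mol_graph` stores, per atom: element, atomic number $Z$, formal charge,
implicit hydrogen count $h$, an aromatic flag, and the valence electron
count $Z^v$; per bond: endpoint indices and integer order. Molecules are
read from SMILES (converted to kekulized V2000 connection tables by
OpenBabel) or SDF/MDL files; a record that fails to parse becomes a
placeholder that propagates a typed `parse_failure` missing value through
every descriptor rather than aborting the batch.

Descriptor values depend on preprocessing conventions, so preprocessing is
explicit and policy-driven (`preprocess_policy()`):

* **Hydrogen mode.** Every in-scope descriptor is defined on the
  hydrogen-suppressed graph; explicit hydrogens are folded into per-atom
  counts (this is what makes literature values of, e.g., the Balaban index
  reproducible). The inverse ("add") mode exists for completeness.
* **Implicit hydrogens** are inferred from a standard valence model
  (default valence of the element, charge-adjusted, minus the bond-order
  sum); metals get no phantom hydrogens.
* **Aromaticity** is perceived by a documented SSSR/Hückel-style model: a
  perceived ring is aromatic when every ring atom can contribute to the π
  system (a double bond, a delocalization flag carried by the input, or an
  N/O/S lone pair) and the π count is $4k+2$. The model name is recorded in
  result metadata (`aromaticity_model = "sssr-huckel"`), because differing
  perception models are a known source of inter-package descriptor
  disagreement. We deliberately implement one simple, reproducible model
  rather than guessing at any particular toolkit's.
* **Kekulization** assigns alternating single/double orders inside aromatic
  systems via a small backtracking perfect matching over atoms that require
  a double bond (aromatic carbons and pyridine-type nitrogens).
* **Desalting** keeps the largest connected component by heavy-atom count.

`preprocess()` is deterministic and idempotent for a fixed policy, and both
properties are tested.

**Disconnected molecules** (without desalting): descriptors that need a
connected graph — anything built on the distance or detour matrix, and
Balaban J — return a `missing_value` with reason `"disconnected"`, because
a topological distance across fragments is undefined. Additive descriptors
(atom counts, Zagreb sums, chi sums) simply sum over fragments.

## Graph matrices

* **Distance matrix**: all-pairs shortest path lengths by breadth-first
  search (via igraph).
* **Detour matrix**: all-pairs *longest simple path* lengths. This is
  NP-hard in general, but chemical graphs are sparse and articulation-point
  rich. The implementation finds the biconnected blocks and cut vertices
  (standard low-link decomposition), solves each block exactly by
  exhaustive depth-first search, and merges: for atoms $u, v$ in different
  blocks the longest path decomposes uniquely along the chain of
  articulation points joining them, so block-internal longest paths are
  summed along the block-cut tree. Merging is implemented by gluing blocks
  one at a time at their shared cut vertex
  ($d(u,v) = d(u,a) + d(a,v)$). The result is verified against a naive
  whole-graph exhaustive search on every test graph. There is no default
  time budget — an exact result is preferred — but callers can set one
  (`time_budget`), which returns a typed `timeout` instead of hanging.
* **Spectral aggregates**: both matrices (and the adjacency matrix) share a
  13-aggregate suite computed from the eigenvalues
  $\lambda_1 \ge \dots \ge \lambda_n$ and the leading eigenvector $c$:
  SpAbs, SpMax, SpDiam, SpAD, SpMAD, LogEE, SM1, VE1–VE3, VR1–VR3. LogEE
  (the log of the Estrada-like index $\sum_i e^{\lambda_i}$) is always
  routed through the shifted log-sum-exp
  $\mathrm{lse}(x) = x^* + \log \sum_i e^{x_i - x^*}$, $x^* = \max_i x_i$,
  which stays finite where the naive form overflows; a regression test
  exercises spectra of magnitude $10^3$–$10^4$.

**Numerical choices.** The leading eigenvector's sign is arbitrary, so only
absolute components enter VE/VR, making those aggregates sign-invariant.
When the top eigenvalue is numerically degenerate the eigenvector basis is
solver-dependent; the bundle flags this (`degenerate_top`) and VR values on
such graphs may legitimately differ between eigensolvers. A VR term with a
vanishing eigenvector component on a bonded atom returns
`missing_value("divide_by_zero")` rather than infinity.

## Descriptor families

Thirteen families are implemented (preset sizes in parentheses): ABCIndex
(2), AtomCount (16), BalabanJ (1), Chi (56), DetourMatrix (14),
DistanceMatrix (13), EccentricConnectivityIndex (1), Framework (1),
KappaShapeIndex (3), MolecularId (12), RingCount (10, extensible),
WienerIndex (2), ZagrebIndex (4) — 135 descriptors in the default full
calculator.

Points where the design was genuinely open, and the choices made:

* **Chi preset composition (56).** Orders were chosen as: path 0–7, chain
  (ring-containing) 3–7, cluster 3–6, path/cluster 4–6, each in simple- and
  valence-delta variants (40), plus averaged path variants 0–7 in both
  deltas (16). Subgraph shape classes follow the Kier–Hall taxonomy:
  *chain* contains a cycle; acyclic subgraphs are *path* (max degree 2),
  *cluster* (branched, star-like: no 3-edge path), or *path/cluster* (the
  rest). Enumeration is by depth-first extension over edge sets (unique by
  construction), never by substructure pattern matching, which is what
  makes high orders affordable; equality with an exhaustive
  subset-classification oracle is asserted on random graphs.
* **Valence delta.** $\delta^v = Z^v - h$ for second-row atoms,
  $(Z^v - h)/(Z - Z^v - 1)$ beyond, the Kier–Hall convention. Formal charge
  does not enter $\delta^v$ in this implementation.
* **Kappa indices** are the plain Kier formulas without the alpha
  correction; whether to alpha-correct was ambiguous, and the plain form is
  the one with clean closed-form checks ($\kappa_1 = A$ on a linear chain).
* **MolecularId subsets.** The 12 members are
  $\{$all atoms, H-bearing heteroatoms, C, N, O, halogens$\}$ ×
  $\{$plain, averaged by heavy-atom count$\}$ — a reverse-engineered
  composition chosen to give a coherent 12-member family. The per-atom
  weight is $w(v) = 1 + \frac12\sum_{P \ni v}\prod_{(u,t) \in P}
  (\delta_u\delta_t)^{-1/2}$ over simple paths with endpoint $v$; prefix
  products are carried along the DFS so each is computed once, and the
  cached result must match an uncached path-by-path oracle to $10^{-12}$.
* **RingCount preset** counts SSSR rings of sizes 3–12 by default (10
  counters); the range is a parameter (`max_n`), so macrocycles (14–16
  membered lactone rings, say) need a parameter, not a source edit. Ring
  perception is a minimum cycle basis (Horton-style candidate cycles,
  greedy GF(2)-independent selection) — one documented SSSR, used
  consistently by ring counts, aromaticity, and the spiro/bridgehead
  tallies. `nSpiro` counts atoms in which two SSSR rings meet at exactly
  one atom; `nBridgehead` counts the endpoints of a multi-bond path shared
  by two rings (fused junctions sharing a single bond count as neither).
* **Framework fraction** iteratively deletes degree-1 heavy atoms and
  reports the surviving fraction (Murcko framework over heavy atoms); only
  the count is computed — the framework's atoms are never materialized into
  a substructure, which keeps it linear-time.
* **Modified Zagreb sums** accumulate as exact integer rationals before the
  final division, so, e.g., $1/3 + 1/6 + 1/2 + 1/3 = 4/3$ is bit-exact —
  an implementation detail that exists because naive float summation is a
  documented source of wrong "modified Zagreb index 2" values in other
  software.

## The calculator framework

`descriptor()` objects are pure evaluation units with declared dependencies
on shared intermediates ("dist", "delta", "subg_4", ...). A `calculator()`
keeps them in registration order, which is also the output order of every
result. During `calculate()` each intermediate is resolved once per
molecule through a context cache and discarded afterwards, bounding memory
across large batches; disabling the cache is tested to change nothing but
cost. Failures never escape: they become `missing_value` objects carrying a
typed reason (`parse_failure`, `disconnected`, `empty_graph`,
`divide_by_zero`, `unsupported_atom`, `dependency_failure`, `timeout`) and
the originating descriptor; `strict = TRUE` turns them back into errors for
debugging. Result sets offer `fill_missing()` (default sentinel `NaN`),
`drop_missing()` and `as_mapping()`.

Descriptor arithmetic (`+`, `-`, `*`, `/`, `^` and `combine()`) builds
composite descriptors for interaction terms; a missing operand yields a
missing composite with reason `dependency_failure`, division by zero yields
`divide_by_zero`.

`map_parallel()` distributes molecules (not descriptors) over forked worker
processes in chunks of $\lceil n/(4p) \rceil$, preserves input order
contractually, and is required by test to be identical to the serial run
for $p \in \{2,3,4\}$; on platforms without fork it falls back to a serial
loop with the same semantics.

## The synthetic-graph generators and oracles

Property tests run on generated carbon skeletons (`graph_recipe()` /
`generate_graph()`): paths, cycles, random trees, random connected graphs
(a random tree plus $\lfloor n/3 \rfloor$ extra edges — sparse, like real
molecules), rings with tails, and bridged two-ring systems. Generation is
seed-deterministic. The independent oracles re-derive each improved
algorithm's output by brute force — exhaustive DFS over all simple paths
for the detour matrix (refusing $n > 14$), exhaustive edge-subset
classification for chi (refusing $n > 10$), exhaustive simple-path
enumeration for the molecular ID — and deliberately share no code with the
optimized implementations.

What the generators emulate is the *topology* of small organic molecules:
sparse, connected, articulation-rich graphs with realistic ring sizes.
What they do not emulate: valence constraints (a degree-5 carbon can occur
in a random graph), heteroatom distributions, charges, stereochemistry, or
large-molecule scale. Passing these suites therefore demonstrates
algorithmic correctness of the graph computations, not chemical validity of
inputs; chemical handling is exercised separately on SMILES-built named
molecules. Oracle size caps ($n \le 12$–$14$ for exponential oracles, 50–100
random graphs per suite) were chosen so the whole property suite completes
in a few minutes on one CPU; they are the package's own test-size choices.

## Known limitations

* The aromaticity model is intentionally simple; exotic aromatic systems
  (fused heteroaromatics with unusual charge states, mesoionics) may be
  perceived differently than by full electron-counting toolkits. The model
  is recorded in result metadata for exactly this reason.
* Elements outside the supported table raise at graph construction
  (`unsupported_atom` territory); organometallics are out of scope.
* The detour computation is exact and exponential per block; molecules with
  very large fused-ring blocks can be slow — the optional `time_budget`
  exists for batch robustness, and returns a typed `timeout`.
* VR aggregates on eigenvalue-degenerate graphs are solver-dependent (see
  above); the bundle flags the condition.
* Kappa indices are uncorrected (no alpha), and the MolecularId subset
  definitions are this package's documented reverse-engineering; both are
  stated here so cross-package comparisons are made with open eyes.
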