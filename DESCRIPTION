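Package: topodesc
Title: Topological Molecular Descriptors with a Descriptor/Calculator Framework
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Calculates 2D topological molecular descriptors for use in
    quantitative structure-property relationship (QSPR) modelling. Provides a
    Descriptor/Calculator architecture with per-molecule dependency caching,
    typed missing values returned instead of raised errors, parameterizable
    family presets, descriptor arithmetic, and order-preserving parallel batch
    computation over molecules. Implemented families include atom counts,
    Zagreb and Wiener indices, Balaban J, Kier-Hall chi connectivity by
    depth-first subgraph enumeration, kappa shape indices, eccentric
    connectivity, ring counts, the Murcko framework fraction, the Randic
    molecular ID with path-product caching, atom-bond connectivity indices,
    and the spectral aggregate suites of the distance and detour matrices.
    The detour matrix is computed exactly by articulation-point decomposition
    into biconnected blocks, and spectral log-sum aggregates use the
    numerically stable log-sum-exp evaluation. Molecules are read from SMILES
    or SDF (V2000) files; results are written as CSV from a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    methods,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
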