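Package: longconn
Title: Longitudinal Structural Connectome Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal analysis of white-matter structural
    brain networks built from probabilistic-tractography streamline counts.
    Covers connectome construction (waytotal and maximum normalization,
    symmetrization, absolute and consistency-based thresholding), timepoint
    consistency diagnostics, graph-theory characterization (efficiency,
    characteristic path length, clustering, small-world index against
    degree-preserving null ensembles), Louvain consensus modularity with
    hub classification and modular-connectivity fingerprints, paired
    network-based statistics with permutation family-wise error control,
    white-matter tract attribution of altered connections, and a
    longitudinal statistics layer (paired t-tests with effect sizes,
    FDR correction, repeated-measures correlation, cluster bootstrap).
    Includes a synthetic two-timepoint cohort generator with planted
    sub-network effects so the whole pipeline is testable without
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
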