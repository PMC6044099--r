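Package: wbnscreen
Title: Ligand-Based Virtual Screening with Weighted Burden Number Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline built around weighted
    Burden number (BCUT-style) eigenvalue descriptors. Computes a 179-column
    descriptor table (24 Burden-matrix eigenvalue descriptors over
    electronegativity, Gasteiger charge and atomic lipophilicity diagonals,
    8 simple properties, 147 pharmacophore-pair fingerprint bits),
    down-samples heavily imbalanced binary bioassays into validated training
    sets with one-sample Z-tests, prioritizes descriptors by their
    contribution to the first principal component, screens test libraries by
    panel voting over an ensemble of per-set random-forest classifiers,
    groups screened compounds with reference drugs on a Kohonen
    self-organizing map, and filters promiscuous chemotypes with a
    rejection/demerit structural-alert engine. A seeded synthetic bioassay
    generator exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
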