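Package: trwr
Title: Two-Round Random Walk with Restart for Cancer Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate cancer genes by a two-round random walk with
    restart on a quadruple-layer heterogeneous network of genes, microRNAs,
    lncRNAs and cancers. The gene layer fuses protein-protein interaction and
    pathway evidence and adds a protein-complex feedback weight; RNA layers are
    k-nearest-neighbour functional similarity networks derived from disease
    associations. Includes a leave-one-out cross-validation harness with
    ROC/AUC and top-k% summaries, single-network and two-layer random-walk
    baselines, and a seeded synthetic fixture generator with planted
    cancer-gene signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
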