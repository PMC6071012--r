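Package: nbclda
Title: Naive Bayesian Common-Neighbor Prediction of lncRNA-Disease
    Associations on Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate long non-coding RNA (lncRNA) disease
    associations on a global tripartite (lncRNA-miRNA-disease) or quadruple
    (lncRNA-miRNA-gene-disease) heterogeneous network.  Each candidate pair
    is scored by Laplace-calibrated naive Bayesian posterior odds computed
    from its common neighboring miRNAs, genes, and interacting miRNA-gene
    pairs; scores can be re-weighted by MeSH-based disease semantic
    similarity.  Includes readers and writers for two-column edge-list and
    MeSH tree-number tables, leave-one-out cross-validation with ROC/AUC,
    top-k F1 evaluation, a seeded synthetic network generator with planted
    associations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
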