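Package: csgl
Title: Reaction-Aware Molecule Embeddings via Chemical Synthesis Graph Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Learns molecule embeddings from reaction corpora by combining a
    molecular graph neural network encoder with a chemical synthesis graph
    (CSG): reactions become directed edges between reactant-set and
    product-set nodes, edge relations are built from integer deltas of bond,
    ring, and per-bond-type counts, node embeddings are refined by an
    attention-based CSG neural network, and all parameters are optimized with
    a margin-based translational-distance loss so that reactant embedding
    plus relation embedding approximates the product embedding. Includes
    downstream evaluators for product-prediction ranking (MRR, Hit@K),
    reaction classification, and molecular property prediction, plus a
    template-based synthetic reaction generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Matrix,
    igraph,
    glmnet,
    jsonlite,
    yaml,
    nnet,
    pROC,
    stats,
    utils
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
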