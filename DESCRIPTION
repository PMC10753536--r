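Package: mespool
Title: Molecular Edge-Shrinkage Graph Pooling for Hierarchical Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical molecular property prediction built on an
    edge-shrinkage graph pooling operator. Molecules parsed from SMILES are
    featurized into attributed graphs (120-dimensional atom vectors,
    13-dimensional bond vectors), passed through edge-featured graph
    isomorphism convolution blocks, and coarsened by contracting low-scoring
    bonds into supernodes while preserving high-scoring bonds and the original
    connectivity. Includes a three-block trainable model with summation
    readouts, scaffold-grouped dataset splitting, masked multitask objectives,
    a matrix reverse-mode automatic-differentiation tape used for training,
    supernode-to-atom interpretability traces, synthetic fixture generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    graphics,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
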