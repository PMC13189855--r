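Package: carpqa
Title: Quality Assessment of Protein-RNA Complex Structural Models with Graph Transformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the accuracy of protein-RNA complex structural models
    without access to the native structure. Residues become nodes of a spatial
    interaction graph carrying 66 node and 12 edge feature channels; a
    three-component graph transformer with top-k pooling, protein-RNA edge
    pruning and global-attention-pooling readouts predicts global fold,
    global interface, and per-interface quality scores (CARP scores).
    Also provides the reference-based ground-truth metrics (backbone lDDT,
    interface lDDT, ICS, IPS, protein-RNA interface RMSD, approximate GDT),
    model-ranking statistics (ranking loss, CASP16-style Z-scores, quantile
    selection metrics), stratified cross-validation folds, a multi-task L1
    training loop, and a synthetic decoy generator for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    tibble,
    tidyr,
    generics,
    rlang,
    withr,
    ggplot2,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
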