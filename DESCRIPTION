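Package: ForestMQA
Title: Random-Forest Model Quality Assessment for Protein Structure Decoys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-model quality assessment for protein 3D structural
    models. Ranks the decoys in a per-target pool by a random-forest
    regression estimate of the relative TM-score, computed from three
    statistical-potential energies, four secondary-structure consistency
    features and two solvent-accessibility consistency features. Includes
    a from-scratch deterministic regression random forest with out-of-bag
    permutation importance, a TM-score engine with Kabsch superposition
    and iterative fragment extension, stand-ins for DSSP secondary
    structure and solvent accessibility, parsers for PSIPRED-style and
    accessibility predictions and external energy tables, the full
    training protocol (pool screening, per-pool normalization, five-fold
    target-level cross-validation, hyperparameter grid search), a metric
    suite for comparing quality-assessment methods, and a synthetic decoy
    generator so the entire pipeline is testable without external
    binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
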