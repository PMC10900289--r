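Package: dictox
Title: Drug-Induced Cardiotoxicity Modeling from Chemical and Biological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying drugs by cardiotoxicity concern from
    chemical structure and auxiliary biological data. Provides iterative SMILES
    standardization with physiological-pH protonation, assembly of binary
    cardiotoxicity labels from concern categories with adverse-event
    enrichment, construction of fingerprint, physicochemical-descriptor,
    annotation, Cmax and omics feature spaces with similarity-conditional
    (v-NN) profile imputation, per-feature association statistics,
    structural-alert mining by recursive fragmentation with
    positive-predictive-value filtering, Random-Forest classifiers with
    Youden-J decision-threshold optimization, threshold-scaled soft-voting
    ensembles, and applicability-domain reporting by nearest-neighbor Tanimoto
    similarity. A synthetic-study generator with a planted toxicophore makes
    every stage runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
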