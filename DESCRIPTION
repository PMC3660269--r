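Package: GOSlimPred
Title: Predictability of GO-Slim Terms from Protein Primary Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how well plant GO-slim functional categories
    can be predicted from protein primary structure alone. Provides sequence
    characterization into a 438-dimensional feature vector (physical-chemical
    descriptors, amino-acid monomer and dimer frequencies, three-state
    secondary-structure composition) with expected-value handling of ambiguous
    residues; ontology-aware construction of positive/negative sets per slim
    term under the annotation propagation principle; greedy identity-based
    redundancy filtering; Ward clustering of features under absolute Pearson
    correlation distance and correlation-based (FCBF-style) feature selection;
    imbalance-corrected one-vs-all classification with SMOTE oversampling and
    Gaussian-kernel support vector machines tuned by particle swarm
    optimization under stratified cross-validation; a nearest-neighbour
    alignment-transfer baseline; and prediction propagation up the ontology
    DAG. A synthetic-data generator with planted compositional signal makes
    every stage testable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    kernlab,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
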