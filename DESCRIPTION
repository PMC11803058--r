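Package: classrt
Title: Class-Partitioned Retention-Time Prediction for Liquid Chromatography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) modelling for
    liquid chromatographic retention times. Molecules are classified into a
    functional-group taxonomy by a weighted SMARTS rule engine, one expert
    regressor is trained per compound class from a candidate suite of seven
    algorithms, and queries are routed to the best-fitting submodel by
    taxonomy with a fingerprint-similarity fallback. Training sets can be
    augmented by SMILES enumeration and by similarity-thresholded active
    learning with strict canonical-SMILES leakage control. Includes a
    deterministic synthetic chemical-library generator with known
    retention-time ground truth for end-to-end validation. Chemistry
    primitives (SMILES canonicalization, SMARTS matching, circular
    fingerprints, 2D descriptors) are computed through a bundled RDKit
    bridge, which requires a 'python' interpreter with 'rdkit' importable.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    digest,
    Matrix,
    FNN,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with the rdkit package importable
RoxygenNote: 7.3.3
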