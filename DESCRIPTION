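Package: gruf
Title: Unified Graph Regression for lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary, discrete (shared-protein counts) and continued
    (real-valued intensity) associations between long non-coding RNAs and
    diseases with a unified graph-regression model. Low-rank SVD embeddings of
    the association graph and of the lncRNA and disease similarity graphs are
    linked by partial least-squares bi-regression, giving confidence scores for
    four scenarios: known-known pairs, new lncRNAs, new diseases, and the
    double cold start. Includes segmented k-mer sequence features for lncRNAs,
    a reduced 7-letter alphabet with 3-mer features for proteins, MeSH
    DAG-based disease semantic similarity, construction of non-binary
    association matrices from lncRNA-protein interactions and gene-disease
    associations, task-specific cold-start cross-validation with AUC, AUPR and
    intensity-correlation metrics, and a planted-structure synthetic data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'association-builder.R'
    'disease-semantics.R'
    'evaluation.R'
    'graph-regression.R'
    'gruf-package.R'
    'io.R'
    'methods.R'
    'sequence-features.R'
    'synthetic-data.R'
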