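Package: topofold
Title: Two-Stage Information-Theoretic Planning of Disulfide Cross-Links for Protein Fold Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans disulfide cross-linking experiments that discriminate among
    candidate structural models of a protein. Candidate models are compared at
    the fold level through contact graphs over their common secondary structure
    elements (SSEs); a minimum-redundancy maximum-relevance (mRMR) search over
    entropy and mutual information selects a small "topological fingerprint" of
    SSE pairs that separates the folds, and a second mRMR stage selects residue
    pairs to probe each fingerprint SSE pair by disulfide trapping, accounting
    for threading misalignment and backbone flexibility sampled from an elastic
    network model. Plans are assessed probabilistically (Bayes error, expected
    tie ratio, none-of-the-above ratio) and validated end to end with a
    synthetic model-ensemble generator, simulated cross-link outcomes from a
    ground-truth structure, and ROC/AUC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    pROC,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'structures-io.R'
    'structures-sse.R'
    'topology.R'
    'fingerprint.R'
    'fingerprint-assess.R'
    'crosslink-noise.R'
    'crosslink.R'
    'simulate-fixture.R'
    'simulate.R'
    'config.R'
    'cli.R'
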