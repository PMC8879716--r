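Package: smilegnn
Title: Drug-Drug Interaction Prediction from SMILES and Knowledge-Graph Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) by fusing two complementary
    views of each drug: a structural feature vector derived from the character
    composition of its SMILES string (bag-of-characters counts reduced by PCA)
    and a topological embedding learned from a multi-relational biomedical
    knowledge graph with a two-hop neighborhood-sampling graph neural encoder.
    Drug pairs are scored as the sigmoid of the inner product of the fused
    per-drug features and the model is trained with binary cross-entropy on
    known interactions plus uniformly sampled negative pairs. Includes triple
    parsers (TSV and an n-quads subset), graph density diagnostics, stratified
    cross-validated evaluation (accuracy, AUC, F1), novel-pair ranking, a
    hyperparameter grid sweep, and a synthetic-data generator with a plantable
    interaction signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
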