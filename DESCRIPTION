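Package: ddifuse
Title: Multi-Scale Drug-Drug Interaction Prediction by Attention Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDI) and typed DDI events by
    fusing three per-drug representations: atomic-level embeddings from an
    attribute-masked message-passing network over molecular graphs, local
    embeddings from a relation-typed drug-entity association graph, and
    global embeddings from a ComplEx factorization of a biomedical knowledge
    graph. The three scales are combined by a transformer encoder with
    multi-head self-attention (with concatenation, Hadamard and averaging
    baselines) and scored by a multilayer perceptron pair head, trained with
    binary cross-entropy or a phased cross-entropy/focal-loss schedule for
    long-tailed event classes. Ships a seeded synthetic-data generator
    (molecule grammar, stochastic block-model association graphs, planted
    low-rank knowledge graphs, plantable pair-label rules) so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
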