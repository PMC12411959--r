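Package: ecgraphnet
Title: Graph Convolutional Beat Classification for Annotated Single-Lead ECG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts beat-annotated single-lead electrocardiogram (ECG)
    records into graphs whose nodes are P, QRS and T segments, and classifies
    every beat as normal (N), supraventricular ectopic (S) or ventricular
    ectopic (V) with a graph convolutional network. Provides a synthetic
    annotated-ECG generator with controllable class mixtures and beat
    patterns, a documented CSV+JSON on-disk record format, per-segment
    autoencoder embeddings, a QRS-centered weighted average pooling operator,
    graph-level minority-class augmentation, interpatient cross-validation
    with grid search, soft-voting ensembles, and a pattern/size scalability
    evaluation protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
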