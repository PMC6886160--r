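Package: biowsd
Title: Supervised Biomedical Word Sense Disambiguation with Recurrent and
    Self-Attention Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised word sense disambiguation (WSD) for ambiguous
    biomedical terms from sense-annotated paragraph corpora. Implements two
    interchangeable context encoders built from first principles -- a
    two-layer bidirectional LSTM and a two-layer multi-head self-attention
    (Transformer-style) encoder with sinusoidal positional encoding --
    followed by a shared upper layer: four output-combination structures
    over the two encoder layers, time-wise max-pooling, an optional
    target-word "hint" concatenation, and a dense 256/64 softmax
    classifier. Training uses Adagrad with an exponentially decayed
    learning rate and checkpoint-restore early stopping, in word-specific
    or universal (all words merged) regimes, with majority and weighted
    voting ensembles and a consensus-error report. Ships a synthetic
    corpus generator with controllable sense separability so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
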