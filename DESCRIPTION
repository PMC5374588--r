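Package: bionerel
Title: Joint Neural Extraction of Biomedical Entities and Relations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a joint neural model for biomedical entity
    recognition and relation classification. A character-level
    convolutional network and a shared bidirectional LSTM encode each
    sentence; a greedy BILOU sequence tagger with previous-label feedback
    recognizes entity mentions, and a second bidirectional LSTM over the
    shortest dependency path between entity anchors, stacked on the shared
    encoder, classifies candidate entity pairs. Both heads are trained
    jointly online with AdaGrad, with a pipeline ablation that severs the
    parameter sharing. Includes readers and writers for BioNLP-ST standoff
    and sentence-record (ADE-style) corpora with CoNLL parse sidecars,
    strict-match precision/recall/F1 scoring with cross-validation and an
    error taxonomy, co-occurrence baselines, and a deterministic synthetic
    corpus generator so the full stack is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
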