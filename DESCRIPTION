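Package: lexner
Title: Lexicon- and Radical-Enhanced Neural Named Entity Recognition for
    Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level named entity recognition for clinical narratives
    built around a dual-branch tagger: a transformer encoder with directional
    relative position encoding whose self-attention keys and values are fused
    with entity-dictionary embeddings, feeding (a) a linear-chain CRF that
    recognises entity boundaries and (b) a convolutional head over
    sub-character (radical) features with an angular-margin softmax that
    recognises entity types.  Supports joint training of both branches,
    single-step adversarial perturbation of the character embeddings,
    and confidence-filtered self-training on unlabeled text.  Reads and
    writes CoNLL-style BIO corpora, entity dictionaries and radical tables,
    computes entity-level precision/recall/F1, and generates seeded synthetic
    corpora with planted dictionary entities and type-correlated radicals so
    the full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
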