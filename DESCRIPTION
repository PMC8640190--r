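Package: nervote
Title: Span-Level Majority-Voting Ensembles for Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for combining the span predictions of several named
    entity recognition (NER) models by per-entity majority voting. Reads and
    writes BRAT standoff annotations, assembles entity spans from per-word
    classifier scores (single-label softmax and multi-label sigmoid decoding,
    including nested entities), scores predictions against gold annotations by
    exact span matching (precision, recall, F1, micro and macro averaged),
    profiles results by entity length, training-corpus frequency and label
    consistency, and generates seeded synthetic corpora with controlled class
    distributions and per-model annotation-noise models so the whole pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
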