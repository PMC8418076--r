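Package: tprmetrics
Title: Word-Level Translation Product Metrics and Reading Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes word-level product metrics for translation process
    research from word-aligned sentence pairs: relative reordering (Cross),
    alignment-link crossings (word_cross), word-group crossings with
    multi-word-group handling (seq_cross), aligned syntactic tree edit
    distance change flags (astred_change) over Universal Dependencies parses,
    and the entropy family over multiple translations (HTra, HCross, HSTC).
    Also derives eye-tracking and keystroke dependent variables (first
    fixation duration, total reading time, eye-key span, first-pass and
    regression-path duration) from token-attributed event logs, applies
    per-participant standard-deviation outlier filtering, and augments
    TPR-DB-style per-token TSV tables with all metric columns. Ships a
    deterministic synthetic-data generator for aligned pairs, multi-translator
    ensembles, and fixation/keystroke logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
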