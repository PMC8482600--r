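Package: spacerscope
Title: CRISPR Spacer Target Analysis, PAM Inference and Array Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing CRISPR spacer matches against candidate
    target sequences (protospacers). Finds and filters spacer hits with a
    two-step matched-fraction rule, removes hits falling inside CRISPR arrays,
    clusters repeats by identity, infers protospacer adjacent motifs (PAMs)
    from GC-corrected information content of protospacer flanks, predicts
    CRISPR array transcription orientation from the PAM side, tests
    coding- versus template-strand targeting bias with exact binomial tests,
    and classifies genomes carrying multi-effector compatible CRISPR arrays.
    Includes a fully labelled synthetic-data generator so every stage of the
    pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
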