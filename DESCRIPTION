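Package: concatemeR
Title: Polished Circular Plasmid Sequences from Rolling-Circle Concatemer Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns noisy long sequencing reads of rolling-circle-amplification
    (RCA) concatemers into demultiplexed, polished, full-length circular
    plasmid sequences. Provides splint-free tandem-repeat boundary detection
    using an anchor taken from the read itself, per-read subread splitting and
    consensus calling, length-histogram demultiplexing of plasmid pools,
    circular-aware padding and two-round pileup polishing with homopolymer
    run-length voting, and rotation- and strand-invariant accuracy evaluation
    against circular references. A truth-annotated concatemer read simulator
    with a configurable substitution/insertion/deletion error model and
    systematic homopolymer errors supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
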