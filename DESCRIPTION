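Package: acetrnaopt
Title: Design and Analysis Toolkit for Anticodon-Edited Suppressor tRNA
    Expression Cassettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for engineering and screening anticodon-edited suppressor
    tRNA (ACE-tRNA) expression cassettes. Builds combinatorial cassette
    sequence libraries (5' upstream control elements, 3' trailers,
    stem-stabilising "sticky stem" pair swaps, t-stem variants and
    anticodon-loop saturation) on top of a cloverleaf secondary-structure
    model, generates Golden-Gate-ready duplex oligonucleotides, scores
    dual-luciferase nonsense-suppression screens, derives activity-weighted
    position frequency and significance logos, fits saturating DNA
    dose-response curves (maximal suppression and half-maximal DNA dose),
    quantifies translational fidelity from targeted proteomics peptide
    abundances, and computes comparative-Ct relative transcript quantities.
    A seeded synthetic-data generator emulates every input so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
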