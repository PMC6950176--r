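Package: dumbbellscan
Title: Detection of RNA Polymerase III Dumbbell-Shaped miRNA Cassettes in Retroviral LTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans proviral genomes or long terminal repeat (LTR) sequences of
    retroviruses (in particular foamy viruses) for RNA polymerase III-driven
    microRNA cassettes: ~130 nt dumbbell-shaped (double stem-loop) primary
    miRNA precursors with a minimum free energy at or below -30 kcal/mol,
    flanked by an upstream TATA box and/or gene-internal A/B boxes and a
    downstream poly-T terminator. Includes a self-contained Zuker-style
    nearest-neighbour folding engine with an exhaustive-enumeration oracle,
    an optional ViennaRNA (RNAfold) backend, dot-bracket topology
    classification, mature-arm extraction with seed-identity matching against
    a host miRNA catalog, a synthetic LTR generator with planted cassettes
    for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    tools,
    utils,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
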