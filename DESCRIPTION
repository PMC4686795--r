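Package: hultman
Title: Hultman Numbers and Rearrangement Distance Distributions for
    Multichromosomal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact combinatorics of multichromosomal breakpoint graphs.
    Counts genomes by the number of cycles and paths in the breakpoint
    graph against a chosen identity genome (four Hultman-number families:
    circular, general, linear identity, and fixed numbers of linear
    chromosomes), using exact arbitrary-precision integer recurrences,
    and derives exact distributions and expected values of the algebraic
    (DCJ-like) rearrangement distance between random genomes.  Genomes in
    GRIMM-style text format can be parsed, converted to extremity
    matchings, and their breakpoint graphs decomposed into cycles and
    paths.  Every recurrence is certified against a brute-force
    matching-enumeration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
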