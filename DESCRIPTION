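Package: smurfseq
Title: Simulation, Split-Read Mapping and Copy-Number Profiling for
    Concatenated-Fragment Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for read-counting copy-number analysis with
    concatenated-fragment long reads (SMURF-seq), in which many short
    restriction fragments are re-ligated into a single long molecule and
    sequenced on a nanopore instrument.  Provides a synthetic-genome and
    read simulator with planted copy-number truth and in-silico restriction
    digestion, a split-read seed-and-extend mapper that recovers the
    constituent fragments of each read, fragment- and base-level mapper
    evaluation against simulation truth, and a read-count CNV pipeline:
    variable-width bins of equal unique mappability, bad-bin masking,
    LOWESS GC-bias correction, circular binary segmentation with
    permutation p-values, spurious-segment removal and amplification /
    deletion event calling, plus profile comparison and read downsampling
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
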