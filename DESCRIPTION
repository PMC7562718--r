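Package: phasir
Title: Phased siRNA Locus Detection and Degradome-Based Target Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 21- and 24-nucleotide phased siRNA (phasiRNA) loci from
    small-RNA read libraries with a nine-cycle sliding-window phase score,
    scores small RNA:transcript complementarity with a mispair penalty scheme
    that tolerates G:U wobble, classifies degradome (PARE) cleavage-site
    signals into categories 0-4, and calls sliced phasiRNA targets from the
    diagnostic tag at the position paired with sRNA nucleotide 10. Includes a
    synthetic-data generator with planted ground truth (phased registers,
    trigger cleavage sites, target cleavage spikes) for end-to-end recovery
    benchmarking, and a mutant-dependence classifier for replicated
    wild-type/mutant count comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
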