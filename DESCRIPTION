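Package: pseudoref
Title: Pseudo-Reference-Based Transcriptome Assembly Decision Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decide how to assemble the transcriptome of a species whose own
    genome is unsequenced. Estimates the genetic distance between the query
    species and a candidate pseudo-reference (a close relative's genome) from
    marker or ortholog sequences, predicts the read-mapping mismatch budget
    that maximizes the unique mapping rate via a linear model trained on
    virtual mutated genomes, chooses among reference-based,
    pseudo-reference-based and de novo strategies, and scores resulting
    assemblies with per-gene coverage, reconstruction rate and the area under
    the cumulative coverage curve. Includes an exact mismatch-bounded read
    mapper, a transition/transversion-preserving genome mutagenesis
    simulator, an RNA-seq read simulator with truth logs, and a seeded
    synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    yaml,
    generics,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
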