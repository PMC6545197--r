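Package: backsplicer
Title: Group I Intron Back-Splicing Analysis on Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the removal of giant mitochondrial group I introns by RNA
    back-splicing from short permuted precursor transcripts. Provides circular
    genome coordinate arithmetic with origin-spanning features, a group I
    splicing state machine (cis-splicing, back-splicing, intron
    circularization), enumeration of diagnostic splice junctions, a
    junction-spanning read classifier with splicing-efficiency statistics,
    an in-silico PCR discriminator of circular versus linear RNA templates,
    and a synthetic mito-transcriptome read simulator with ground-truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
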