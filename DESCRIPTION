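Package: quasipop
Title: Low-Frequency Variant Calling and Read-Backed Co-Occurrence for Phage Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing localised genetic heterogeneity in deep-sequenced
    bacteriophage populations. Simulates quasispecies-like phage populations with
    planted single-nucleotide variants on weighted haplotypes and paired-end reads
    with a known truth table; implements sliding-window quality trimming and
    mean-quality read filtering; maps reads with a seed-and-extend ungapped
    aligner (plus a SAM reader for externally mapped data); builds per-position
    pileups with mate-overlap resolution; derives a sample consensus and calls
    low-frequency variants under coverage and frequency thresholds with a
    multi-configuration two-standard-deviation consensus filter; computes
    read-backed pairwise SNP co-occurrence; and localises variants on annotated
    gene modules with codon-level consequence calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
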