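Package: skewdomain
Title: Allelic Skew, Spike-In Calibrated ChIP-seq and Cohesin Domain
    Quantification on Synthetic Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Skewdomain", "Developers", email = "skewdomain@example.org",
           role = c("aut", "cre"))
Description: Tools connecting regulatory-element activity to cohesin
    recruitment: phased-genome allelic-skew inference with exact binomial
    and beta-binomial tests, spike-in calibrated ChIP-seq normalization
    with down-sampling factors, sub-TAD inside/outside coverage-ratio
    quantification, neutral-region discovery with in-silico DpnII
    digestion and viewpoint design, insertion-edited genome bookkeeping
    with junction-read classification, and allele-resolved motif
    enrichment. A synthetic diploid data generator emulates donors
    carrying phased heterozygous variants, activity-coupled cohesin
    signal, spike-in read mixtures and insertion-edited loci so the whole
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
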