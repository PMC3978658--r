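Package: centrochip
Title: Simulation and Analysis of ChIP-Seq Centromere Enrichment in
    Repeat-Rich Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying ChIP-seq enrichment at repetitive
    centromeres of kinetoplastid-like genomes. Generates seeded synthetic
    genomes with AT-rich tandem-repeat centromere arrays, planted
    near-identical duplicates and a palindromic 177 bp repeat
    minichromosome contig; simulates 49 bp single-end ChIP and input
    libraries with sequencing artifacts and applies the matching
    read-cleaning rules; maps reads allowing up to two mismatches with
    uniform random assignment of multi-mapping reads; computes
    input-normalised enrichment ratios in 150 bp nonoverlapping windows,
    background levels and centromere peak calls; diagnoses false-positive
    peaks caused by cross-mapping between near-identical repeats; and
    deduces protein subcomplexes from affinity-purification mass
    spectrometry evidence under a two-peptide inclusion rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    igraph,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
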