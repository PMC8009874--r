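Package: exocap
Title: Exome Capture Probe Design and Cross-Platform Variant Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for designing hybridization capture probes against an
    annotated genome and for auditing the resulting exome sequencing data
    against matched whole-genome sequencing. The design half consolidates
    coding targets, tiles variable-length candidate probes, filters them by
    k-mer repetitiveness and approximate-match uniqueness, scores them by
    melting temperature and sequence composition, and selects probes in
    sliding windows, reporting direct and indirect target coverage. The
    analysis half hard-filters paired platform call sets, classifies variants
    as common or platform-exclusive, tabulates consequence categories,
    computes Ti/Tv ratios and allele-count spectra, and quantifies per-gene
    platform bias and sex-linked detection bias. A seeded synthetic-fixture
    generator produces toy genomes, annotations and paired call sets with
    controlled repeat content, paralogy, sharing and error structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
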