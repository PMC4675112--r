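Package: nuwtscan
Title: Detection and Donor Attribution of Nuclear Endosymbiont Insertions
    from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects nuclear insertions of endosymbiont (Wolbachia) DNA in
    a host genome from short sequencing reads and attributes each insertion
    to one of two divergent donor supergroups.  Implements competitive
    (mutually exclusive) read mapping against multiple reference genomes
    with explicit similarity and aligned-length acceptance thresholds,
    reciprocal-mapping read specificity classification, covered-base
    insert-size estimation, reference-guided consensus contigs with N50
    statistics stratified by prophage regions, detection of genes
    represented in both donors' inserts, and allele-level haplotype
    clustering with premature stop-codon screening.  Ships a synthetic-data
    generator (donor genomes, host genome with inserts, error-bearing
    paired-end reads) with complete ground truth so every stage of the
    pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
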