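Package: censatr
Title: Centromeric Satellite Discovery and CENP-A Chromatin Annotation from
    Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds a centromeric satellite sequence database from
    whole-genome shotgun reads with mate-pair information and annotates it
    with CENP-A chromatin state from ChIP-seq reads.  Phase I detects
    tandem repeats, clusters monomer consensi into satellite families,
    annotates reads, and anchors families to centromere gaps through
    pericentric enrichment and mate-pair linkage networks.  Phase II
    reformats the read database into canonical 50-mers, subtracts
    assembly-matching k-mers, and classifies single- versus multi-copy
    k-mers against a calibrated single-copy depth model.  Phase III scores
    k-mers for CENP-A ChIP enrichment against sampled genomic background
    replicates, classifies reads as CENP-A positive or negative, and
    resolves monomer subtypes by windowed k-means clustering, F84/UPGMA/
    neighbor-joining phylogenies, and mate-pair subtype networks.  A
    synthetic genome simulator with complete planted truth (satellite
    arrays, transposable-element insertions, assembly gaps, paired
    shotgun reads, and ChIP reads) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    phangorn,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
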