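Package: histokit
Title: Strand-Resolved Histone Inheritance and Lineage Clone Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for replication-coupled histone recycling
    experiments. Computes eSPAN (enrichment and sequencing of
    protein-associated nascent DNA) Watson/Crick strand-partition bias
    profiles around replication origins with BrdU-control normalization
    and smoothing; classifies differential peaks between conditions and
    scores annotation-type enrichment of differential versus stable
    peaks; assigns peaks to A/B chromatin compartments; classifies
    enhancers from H3K4me1/H3K4me3/H3K27ac/H3K27me3 occupancy; quantifies
    FPKM signal in genome bins and anchor-centered meta-profiles with
    change-ratio correlation across marks; calls lineage-barcode clones
    from cell/UMI/barcode triples with read, hamming-distance and UMI
    thresholds; and provides seeded synthetic-data generators with ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
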