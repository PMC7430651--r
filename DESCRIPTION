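Package: ecclineage
Title: Detection, Inheritance and Quantification of Extrachromosomal
    Circular DNA in Aging Yeast Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis of extrachromosomal circular DNA (eccDNA)
    from Circle-Seq alignment data in replicatively aging Saccharomyces
    cerevisiae. Calls circles from unique genomic regions by clustering
    junction-spanning (soft-clipped and outward-oriented discordant) reads, and
    from repetitive regions by resolving multi-mapping reads through
    alternative-hit score ratios. Classifies circle inheritance across
    young/progeny/aged subpopulations into classes I-V, estimates de novo
    circle formation rates, quantifies circle abundance with median-of-ratios
    and spike-in normalization, and tests genomic-feature and sequence-motif
    enrichment with exact tests under Benjamini-Hochberg correction. Includes a
    synthetic Circle-Seq read simulator (toy genome, planted circle cohorts
    with designed inheritance, junction reads, multi-mapping repeat reads,
    spike-in plasmids) so every stage is testable without deposited sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
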