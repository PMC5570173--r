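Package: plantbgc
Title: Detection and Transcriptome-Based Prioritization of Plant
    Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate plant biosynthetic gene clusters (BGCs)
    from annotated genomes using a biosynthetic protein-domain library, a
    gene-density-aware chaining rule with a dynamic kilobase cutoff, and
    sequence-identity subclass grouping so tandem arrays of near-identical
    genes count once.  Prioritizes candidate clusters with transcriptome
    data: within-cluster coexpression networks, ego networks, Louvain-based
    inter-cluster linkage, and a distance-matched one-sided Mann-Whitney
    test of within-cluster coexpression against a genomic background.
    Includes a comparative (ClusterBlast-style) locus search and a synthetic
    genome/expression generator with planted, truth-tracked structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    withr,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
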