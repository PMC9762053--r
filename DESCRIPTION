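Package: pancoex
Title: GWAS-Driven Pan-Genome Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds trait-filtered Pearson co-expression networks per genome
    from TPM expression matrices, unions them into a pan-genome co-expression
    network ("pan-network") with occurrence-based classification of edges into
    core, near-core, dispensable and private categories, assigns GWAS hits to
    genes via genic and strand-aware promoter windows, extracts trait-specific
    subnetworks with hub and pleiotropy statistics, and performs hypergeometric
    GO over-representation tests with Benjamini-Hochberg FDR control. Includes
    a synthetic multi-genome expression simulator with planted co-expression
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
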