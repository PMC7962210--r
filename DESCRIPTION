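Package: numtforge
Title: Genome Assembly Auditing: NUMT Discovery, Read-Depth Copy Number,
    Scaffold Tidying and Structural-Variant Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for auditing de novo genome assemblies. Discovers
    nuclear mitochondrial DNA (NUMT) fragments from homology hits against a
    doubled circular mitochondrial genome, compresses them to unique genomic
    intervals and merges them into blocks; estimates locus and gene-family
    copy number from per-base read depth normalised to the modal depth of
    BUSCO single-copy genes; classifies assembly scaffolds as haplotigs,
    low-coverage artefacts or collapsed repeats from depth-bin profiles and
    self-mapping; builds two-platform structural-variant consensus sets with
    cross-sample overlap and gene/exon annotation; and ships a fully
    deterministic synthetic-data generator (toy genomes with planted NUMTs,
    tandem gene arrays, haplotigs, Poisson depth and jittered SV call sets)
    so every analysis is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
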