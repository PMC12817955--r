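Package: texmap
Title: Post-Transcriptional Landscape Mapping from dRNA-Seq and RIP-Seq
    Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for charting the post-transcriptional
    regulatory landscape of an archaeal (or bacterial) genome from
    strand-specific sequencing tracks. Detects transcription start sites
    (TSS) and transcript processing sites (TPS) from paired +/-TEX
    dRNA-seq read-start tracks with an exact conditional binomial
    rate-ratio test, annotates novel antisense RNAs, small RNAs and small
    ORFs by matching orphan/antisense TSSs to Term-seq termination sites,
    calls protein-RNA interaction sites from RIP-seq coverage as runs of
    elevated log2 fold change, and integrates expression: antisense/mRNA
    pair correlation, direction-agreement summaries, protein-level
    coupling, and bound-versus-unbound trajectory comparisons. A seeded
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads. All tabular results are tibbles
    designed for piped dplyr/ggplot2 workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
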