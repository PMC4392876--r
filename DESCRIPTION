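Package: cistromix
Title: Transcription-Factor Cistrome Consensus and Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for replicate-consensus calling of transcription-factor
    ChIP-seq peaks, cross-cell-type shared/unique classification, peak-to-gene
    annotation by transcription start site windows, genomic feature
    distributions against genome background, summit-centred tag-density
    profiling, two-stage NanoString nCounter count normalisation
    (positive-control spike-ins then reference-gene geometric means),
    anchor-gene Pearson correlation ranking, hierarchical clustering of
    z-scored expression, tumour-versus-normal and stage-stratified group
    statistics, knockdown t-tests with Venn overlap, and seeded synthetic-data
    generators so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    jsonlite
Config/testthat/edition: 3
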