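Package: epicoloc
Title: Epigenomic Co-Localization Profiling of Genomic Region-Set Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests families of genomic region sets (for example, classes of
    non-coding RNA loci) for enrichment or depletion in collections of
    epigenomic annotation tracks (chromatin states, histone modification
    peaks, transcription factor binding sites). Significance is assessed
    against an empirical null obtained by repeatedly sampling pseudo-classes
    from the pooled universe of all query sets, followed by a chi-square
    test and Benjamini-Hochberg correction. The resulting signed -log10
    adjusted p-value profiles are filtered, hierarchically clustered
    (Chebyshev distance, Ward agglomeration) and compared by Pearson
    correlation to classify the families by epigenomic similarity. A
    synthetic-study generator with planted, known enrichment effects makes
    every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    ape,
    pheatmap,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
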