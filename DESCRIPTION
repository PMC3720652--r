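Package: gobylite
Title: Chunked Scatter/Gather Engine and Statistics for High-Throughput
    Sequencing Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of the analysis core of a
    grid-based high-throughput sequencing pipeline: byte-offset chunk
    planning with array-job semantics and failure-tolerant gather, a
    four-function plugin contract, fragment counting over annotations with
    RPKM and upper-quartile normalization, heptamer priming-bias read
    weights, Fisher-exact and Student-t differential expression with
    Benjamini-Hochberg adjustment, strand-aware per-cytosine bisulfite
    methylation-rate estimation with region aggregation, multi-group
    differential methylation and VCF/IGV output, pathogen-contamination
    screening filters, and a bisulfite/expression simulator providing
    ground truth for every analysis step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    parallel,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
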