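Package: stringaggr
Title: Aggregation and Visualization of STRING Functional Enrichment
    Across Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automates functional-enrichment workflows built on the STRING
    web service for experiments with many differential-expression
    comparisons. Parses per-comparison gene/fold-change tables, splits
    genes into up- and downregulated sets, retrieves enrichment records
    for five knowledge bases (KEGG, GO Process, GO Function, GO
    Component, Reactome) through a pluggable transport that also runs
    fully offline against fixture tables, aggregates terms across
    comparisons into per-knowledge-base results and summary tables
    (minimum FDR, occurrence, union and intersection of matched genes),
    and renders clustermaps and bubble plots of the aggregates. Includes
    a constructive fixture generator with exact ground truth for offline
    testing and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pheatmap,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
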