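Package: sexbiasnet
Title: Network Analysis of Sex-Biased Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to relate sex-biased gene expression to the structure of a
    functional-coupling gene network. Calls per-condition sex bias with a
    moderated Welch test and Benjamini-Hochberg false discovery rates,
    quantifies crosstalk between bias groups against a degree-preserving
    edge-swap null, correlates bias with node degree and ranks sex-biased
    hub genes, tests whether inparalog duplicates retain the same bias by
    resampling, and discovers sex-biased network modules with Markov
    clustering and a shared-neighbor clusterer, scoring their Gene Ontology
    enrichment against size-matched random modules. A synthetic-data module
    generates scale-free networks, expression matrices, ortholog groups and
    annotations with planted structure so that every stage of the analysis
    can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
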