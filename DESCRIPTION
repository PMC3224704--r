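Package: cistronet
Title: Operon Refinement and Mutual-Information Regulatory Networks for
    Bacterial Transcriptome Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-regulatory networks in bacteria from
    multi-platform expression compendia. Refines a whole-genome operon map by
    supervised classification of same-strand adjacent gene pairs using
    functional similarity, gene-order conservation, intergenic distance and
    expression correlation; aggregates expression to cistrons; infers a
    mutual-information network around regulator cistrons with data-processing-
    inequality pruning; and characterizes the resulting hub-centered modules by
    Fisher's-exact functional enrichment with q-values and by expectation-
    maximization promoter-motif discovery calibrated against letter-shuffled
    nulls. Includes a seeded synthetic-data generator that emulates operon
    co-expression structure, regulator-target dependencies and planted
    promoter motifs, so every stage can be benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    igraph,
    Biostrings,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
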