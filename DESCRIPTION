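Package: condkg
Title: Condition-Based Precision-Medicine Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Build, store, and query condition-based pharmacogenomic
    knowledge graphs. Relationships are hyper-triples whose subject or
    object may itself be another relationship, so that a genotype can
    condition a drug response and one event can cause another. The
    package provides four machine-checkable knowledge patterns (side
    effects, drug sensitivity, drug mechanisms, drug indications),
    lossless reification into a conventional property graph with
    relation nodes and from/to edges, JSON Lines and CSV serialization
    for graph-database bulk import, controlled-vocabulary entity
    disambiguation with ambiguity flagging, condition-aware query
    applications (personalized drug suggestion, pharmacogenomics
    profiles, medication synergy, shared-mechanism repurposing
    hypotheses), and strictly grounded natural-language rendering of
    subgraphs for downstream language-model interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
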