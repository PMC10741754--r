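Package: sonokg
Title: Knowledge Graphs from Narrative Ultrasound Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns the narrative free text of ultrasound reports into
    computable knowledge graphs. A clause-level term network is built from
    each report, tag-sequence rules convert it into entity-relation triples
    (a simple knowledge graph), word-vector synonym tables normalise
    attribute vocabulary, and a hyperplane-translation embedding model with
    a Gaussian proximity kernel (KGCM) restores the head entities that
    report writers habitually omit in follow-on clauses. Results can be
    serialised as RDF/XML, Turtle and GraphML, and evaluated against gold
    triples with precision/recall/F1 and a domain-extraction index. A
    synthetic report generator with gold annotations makes the whole
    pipeline testable without access to clinical data.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
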