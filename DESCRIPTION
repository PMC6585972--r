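Package: phenotrack
Title: Ontology-Driven Data Management for Plant Phenotyping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates the heterogeneous records of high-throughput plant
    phenotyping experiments - plants, plots, pots, sensors, images, events and
    measurements - around a semantic store. Every experimental object carries a
    structured URI; relations between objects live in a subject-predicate-object
    triple graph with class subsumption and transitive-closure inference;
    experimental events (moves, sowing, harvest, troubles) and web-style
    annotations are recorded against objects and inherited along part-of chains.
    From move events the package reconstructs each object's residence intervals,
    stitches per-object environmental time series across installations with full
    provenance, and computes thermal time from sowing. Observed variables follow
    the trait-method-unit model with SKOS-style mappings to reference ontologies,
    hybrid semantic/quantitative queries select objects by class, events,
    relations and measured values, and a robust replicate screen flags anomalous
    plants and traces their origin (e.g. seed lot) through the graph. A
    deterministic generator simulates complete glasshouse and field experiments
    so every component is testable without external data.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
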