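Package: coopquery
Title: Cooperative Natural-Language Query Answering over Relational
    Biological Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Translates short English queries over an arbitrary relational
    biological database into (unions of) SQL queries.  An ontology of
    concepts, binary associations, a type hierarchy and Horn-style
    inference rules is merged with the database scheme into a schema
    graph; query terms are bound to graph nodes and connected by
    deterministic shortest-path/Steiner search into a logical query
    graph; Datalog-style rule unfolding and registered external
    functions (identifier mappers, organism mappers, sequence-homology
    checks) expand the query cooperatively, so that answers derivable
    by rules are returned even when no stored row answers the query
    directly.  Includes a worked four-table gene/protein/ortholog
    example world, a randomized world generator for property testing,
    and a small evaluator for the restricted SQL dialect the generator
    emits.
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
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
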