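test_that("imperative queries decompose into head noun plus modifiers", {
  w <- delta_world()
  p <- parse_query("List all growth control genes", w$lexicon)
  expect_equal(p$query_type, "imperative")
  expect_equal(p$verbs, "list")
  expect_equal(nrow(p$roles), 1L)
  expect_equal(p$roles$head_lemma, "gene")
  expect_setequal(p$roles$modifiers[[1]]$lemma, c("growth", "control"))
})

test_that("prepositional phrases open a new role and record the preposition", {
  w <- delta_world()
  p <- parse_query("List all growth control genes in dogs", w$lexicon)
  expect_equal(nrow(p$roles), 2L)
  expect_equal(p$roles$head_lemma[2], "dog")
  expect_equal(p$roles$prep[2], "in")
  expect_true(any(p$dependencies$relation == "prep_in"))
})

test_that("Does/Is questions classify as existential", {
  w <- delta_world()
  p <- parse_query("Does gene 55245 encode a protein", w$lexicon)
  expect_equal(p$query_type, "interrogative-existential")
  expect_equal(p$roles$head_lemma[1], "gene")
  expect_equal(p$roles$modifiers[[1]]$surface, "55245")
  expect_true("encode" %in% p$verbs)
  p2 <- parse_query("Which genes encode proteins", w$lexicon)
  expect_equal(p2$query_type, "interrogative")
})

test_that("empty or role-free queries raise a parse error", {
  w <- delta_world()
  expect_error(parse_query("", w$lexicon), class = "coopquery_parse_error")
  expect_error(parse_query("   ", w$lexicon), class = "coopquery_parse_error")
  expect_error(parse_query("in of the", w$lexicon),
               class = "coopquery_parse_error")
})

test_that("matching binds nouns to concepts and literals to columns", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all growth control genes", w$lexicon), sg)
  head_row <- m[m$part == "head", ]
  expect_equal(head_row$node, "concept:gene")
  expect_equal(head_row$match_kind, "exact-concept")
  expect_equal(head_row$score, 1)
  lit <- m[m$match_kind == "value-literal", ]
  expect_equal(lit$node, "attr:Protein.Function")
  expect_equal(lit$literal, "growth control")
})

test_that("organism objects bind as value literals with stored capitalization", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all genes in dogs", w$lexicon), sg)
  dog <- m[m$surface %in% c("dogs", "dog") | m$lemma == "dog", ]
  expect_equal(unique(dog$match_kind), "value-literal")
  expect_equal(unique(dog$literal), "Dog")
  expect_true("attr:Gene.Organism" %in% dog$node)
})

test_that("identifier literals keep all candidate columns for the connector", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("Does gene 55245 encode a protein", w$lexicon), sg)
  id <- m[m$literal %in% "55245", ]
  expect_gte(nrow(id), 2L)
  expect_true(all(startsWith(id$node, "attr:")))
  expect_equal(length(unique(id$candidate_group)), 1L)
})

test_that("transitive verbs bind to association names", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("Does gene 55245 encode a protein", w$lexicon), sg)
  expect_true("assoc:encode" %in% m$node)
})

test_that("unmatched tokens are dropped with a note, not an error", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all xyzzy genes", w$lexicon), sg)
  expect_true("xyzzy" %in% attr(m, "dropped")$surface)
  expect_true("concept:gene" %in% m$node)
})

test_that("a query with no groundable content word is rejected", {
  sg <- delta_graph()
  w <- delta_world()
  expect_error(
    match_terms(parse_query("List all xyzzy wibbles", w$lexicon), sg),
    class = "coopquery_no_match_error")
})

test_that("plural, singular and case variants bind identically", {
  sg <- delta_graph()
  w <- delta_world()
  node_of <- function(q) {
    m <- match_terms(parse_query(q, w$lexicon), sg)
    m$node[m$part == "head"][1]
  }
  expect_equal(node_of("List all genes"), "concept:gene")
  expect_equal(node_of("List all Genes"), "concept:gene")
  expect_equal(node_of("list the gene"), "concept:gene")
  expect_equal(node_of("LIST ALL GENES"), "concept:gene")
})
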