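fixture_lqg <- function(query = "List all growth control genes in dogs") {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query(query, w$lexicon), sg)
  attach_constraints(connect_matches(m, sg), m)
}

test_that("depth 0 yields exactly the base derivation", {
  sg <- delta_graph()
  der <- expand_derivations(fixture_lqg(), sg, max_depth = 0L)
  expect_equal(nrow(der), 1L)
  expect_equal(der$depth, 0L)
  expect_length(der$rules_applied[[1]], 0L)
})

test_that("negative depth is a parameter error", {
  sg <- delta_graph()
  expect_error(expand_derivations(fixture_lqg(), sg, max_depth = -1L),
               class = "coopquery_parameter_error")
})

test_that("two-step unfolding reaches the ortholog, homolog and encoding routes", {
  sg <- delta_graph()
  der <- expand_derivations(fixture_lqg(), sg, max_depth = 2L)
  expect_equal(nrow(der), 5L)
  expect_equal(sort(table(der$depth), method = "radix"),
               sort(table(c(0L, 1L, 2L, 2L, 2L)), method = "radix"))
  rules <- vapply(der$rules_applied, paste, "", collapse = "+")
  expect_setequal(rules, c("", "r1", "r1+r2", "r1+r3", "r1+r4"))
  preds <- vapply(der$atoms, function(a)
    paste(sort(vapply(a, function(x) x$predicate, "")), collapse = ","), "")
  expect_true(any(grepl("ortholog", preds)))
  expect_true(any(grepl("homolog", preds)))
  expect_true(any(grepl("encode", preds)))
})

test_that("expansion equals an exhaustive unfolding oracle modulo renaming", {
  sg <- delta_graph()
  lqg <- fixture_lqg()
  for (d in 0:2) {
    der <- expand_derivations(lqg, sg, max_depth = d)
    got <- vapply(der$atoms, coopquery:::canon_atoms, "")
    base <- coopquery:::lqg_to_atoms(lqg, sg)
    want <- oracle_unfold(base$atoms, sg$ontology$rules, d)
    expect_setequal(got, want)
  }
})

test_that("expansion terminates on recursive rule sets", {
  w <- delta_world()
  o <- ontology(
    concepts = w$ontology$concepts,
    associations = list(
      list(name = "alias", source = "gene", target = "gene"),
      list(name = "partof", source = "gene", target = "organism")),
    rules = c("partof(X, Y) <- alias(X, Z), partof(Z, Y)",
              "alias(X, Y) <- alias(Y, X)"),
    types = w$ontology$types)
  sg <- build_schema_graph(w$db, o, w$registry, w$lexicon)
  m <- match_terms(parse_query("List all genes in dogs", w$lexicon), sg)
  lqg <- attach_constraints(connect_matches(m, sg), m)
  der <- expand_derivations(lqg, sg, max_depth = 3L)
  expect_gt(nrow(der), 1L)
  expect_true(all(der$depth <= 3L))
  expect_lt(nrow(der), 50L)
})

test_that("mock external functions answer the bundled lookups", {
  reg <- delta_world()$registry
  expect_equal(call_function(reg, "OrganismMapper", "LOC608882"), "Dog")
  expect_equal(call_function(reg, "OrganismMapper", "55245"), "Human")
  expect_equal(call_function(reg, "IDMapper", "UQCC", "LOC608882"), "Ortholog")
  expect_equal(call_function(reg, "IDMapper", "LOC608882", "UQCC"), "Ortholog")
  expect_equal(call_function(reg, "GeneMapper", "UQCC"), "55245")
  expect_true(is.na(call_function(reg, "GeneMapper", "NOPE999")))
})

test_that("registry contracts: arity, registration, live entries", {
  reg <- delta_world()$registry
  expect_error(call_function(reg, "NotThere", "x"),
               class = "coopquery_registry_error")
  expect_error(call_function(reg, "IDMapper", "onlyone"),
               class = "coopquery_registry_error")
  expect_error(call_function(reg, "GeneCards", "UQCC"),
               class = "coopquery_registry_error")
})

test_that("memoized and unmemoized calls agree", {
  w <- delta_world()
  reg <- coopquery:::delta_registry(w$db)
  pairs <- expand.grid(a = w$db$tables$Gene$GeneID, b = w$db$tables$Gene$GeneID,
                       stringsAsFactors = FALSE)
  memo <- mapply(function(a, b) call_function(reg, "Homolog", a, b),
                 pairs$a, pairs$b)
  fresh <- mapply(function(a, b) call_function(reg, "Homolog", a, b,
                                               memoize = FALSE),
                  pairs$a, pairs$b)
  expect_identical(memo, fresh)
})

test_that("the homology mock reflects sequence identity and its threshold", {
  w <- delta_world()
  g <- w$db$tables$Gene
  id_hd <- sequence_identity(g$DNASequence[g$GeneID == "55245"],
                             g$DNASequence[g$GeneID == "LOC608882"])
  expect_gte(id_hd, 0.9)
  reg <- coopquery:::delta_registry(w$db, homology_threshold = 0.9)
  expect_equal(call_function(reg, "Homolog", "55245", "LOC608882"), "Homolog")
  strict <- coopquery:::delta_registry(w$db, homology_threshold = 0.999)
  expect_true(is.na(call_function(strict, "Homolog", "55245", "LOC608882")))
  expect_equal(sequence_identity("ACGT", "ACGT"), 1)
  expect_equal(sequence_identity("ACGT", "ACGA"), 0.75)
  expect_equal(sequence_identity("", "ACGT"), 0)
})
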