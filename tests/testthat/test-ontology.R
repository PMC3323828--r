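test_that("ontology files load, serialize and reload identically", {
  w <- delta_world()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ontology(w$ontology, path)
  o2 <- read_ontology(path)
  expect_equal(o2$concepts, w$ontology$concepts)
  expect_equal(o2$associations, w$ontology$associations)
  expect_equal(purrr::map_chr(o2$rules, "text"),
               purrr::map_chr(w$ontology$rules, "text"))
  expect_equal(o2$types$edges, w$ontology$types$edges)
  expect_equal(o2$undefined_predicates, w$ontology$undefined_predicates)
})

test_that("undefined rule predicates are retained and flagged, not rejected", {
  o <- delta_world()$ontology
  expect_setequal(o$undefined_predicates, c("homolog", "ortholog"))
  expect_length(o$rules, 4L)
})

test_that("an empty ontology file loads without error", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("concepts: []\nassociations: []\nrules: []", path)
  o <- read_ontology(path)
  expect_equal(nrow(o$concepts), 0L)
  expect_equal(nrow(o$associations), 0L)
  expect_length(o$rules, 0L)
})

test_that("rules violating range restriction or arity are rejected", {
  expect_error(parse_rule("function(X, Y) <- alias(X, Z)"),
               class = "coopquery_rule_validation_error")
  expect_error(parse_rule("broken(X Y"), class = "coopquery_rule_parse_error")
  expect_error(
    ontology(concepts = "gene",
             rules = c("p(X) <- gene(X)", "p(X, Y) <- gene(X), gene(Y)")),
    class = "coopquery_ontology_validation_error")
})

test_that("association endpoints must name declared concepts", {
  expect_error(
    ontology(concepts = "gene",
             associations = list(list(name = "partof", source = "gene",
                                      target = "organism"))),
    class = "coopquery_ontology_validation_error")
})

make_random_tree <- function(n, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  parents <- c(NA, vapply(2:n, function(i) sample(nodes[seq_len(i - 1L)], 1L), ""))
  type_hierarchy(tibble::tibble(child = nodes[-1L], parent = parents[-1L]))
}

# exhaustive oracle: intersect full ancestor chains, keep the deepest
oracle_lub <- function(types, th) {
  chains <- lapply(types, coopquery:::type_ancestors, th = th)
  common <- Reduce(intersect, chains)
  depths <- vapply(common, coopquery:::type_depth, integer(1), th = th)
  sort(common[depths == max(depths)])[1L]
}

test_that("least upper bound: singleton, shared parent, and tree oracle", {
  th <- delta_world()$ontology$types
  expect_equal(type_lub("gene", th), "gene")
  expect_equal(type_lub(c("molecular function", "biological process"), th),
               "function")
  expect_equal(type_lub(c("gene", "protein"), th), "identifier")
  expect_error(type_lub("nonexistent", th), class = "coopquery_type_error")

  tree <- make_random_tree(50, seed = 42)
  set.seed(99)
  for (rep in 1:60) {
    pick <- sample(tree$nodes, sample(1:3, 1L))
    expect_equal(type_lub(pick, tree), oracle_lub(pick, tree), info = paste(pick, collapse = ","))
  }
})

test_that("lub is idempotent and monotone under set growth", {
  tree <- make_random_tree(30, seed = 7)
  set.seed(11)
  for (t in sample(tree$nodes, 10L)) {
    expect_equal(type_lub(t, tree), t)
  }
  depth <- function(x) coopquery:::type_depth(x, tree)
  for (rep in 1:40) {
    base <- sample(tree$nodes, sample(1:3, 1L))
    extra <- sample(tree$nodes, 1L)
    expect_lte(depth(type_lub(c(base, extra), tree)),
               depth(type_lub(base, tree)))
  }
})

test_that("type hierarchies reject cycles, multiple roots and orphan parents", {
  expect_error(type_hierarchy(list(c("a", "b"), c("b", "a"))),
               class = "coopquery_type_error")
  expect_error(
    type_hierarchy(tibble::tibble(child = c("a", "a"), parent = c("r", "s"))),
    class = "coopquery_type_error")
})
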