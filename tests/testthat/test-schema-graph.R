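test_that("the example schema graph carries the expected node census", {
  sg <- delta_graph()
  cen <- graph_census(sg)
  expect_setequal(cen$concepts_mapped$concept,
                  c("gene", "protein", "organism", "function"))
  expect_equal(cen$unmapped_concepts, character(0))
  expect_setequal(cen$entity_concepts, c("gene", "protein"))
  expect_equal(cen$value_mapped_concepts, "ortholog")
  expect_equal(cen$function_resolvable_only, "homolog")
  expect_setequal(unique(cen$associations_mapped$association),
                  c("alias", "encode", "function", "partof"))
  expect_equal(cen$associations_unmapped, "has")
  expect_setequal(cen$function_nodes,
                  c("GeneCards", "GeneMapper", "Homolog", "IDMapper",
                    "OrganismMapper"))
  # node taxonomy: concepts, one node per column, one per function
  expect_equal(sum(sg$nodes$kind == "attribute"), 13L)
  expect_true(all(paste0("fn:", cen$function_nodes) %in% sg$nodes$id))
})

test_that("construction is deterministic for identical inputs and seed", {
  w <- delta_world()
  sg1 <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon, seed = 5L)
  sg2 <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon, seed = 5L)
  expect_identical(sg1$nodes, sg2$nodes)
  expect_identical(sg1$edges, sg2$edges)
  expect_identical(sg1$cmap$mu, sg2$cmap$mu)
  expect_identical(sg1$rmap, sg2$rmap)
})

test_that("an empty ontology leaves a graph of database-derived concepts only", {
  w <- delta_world()
  o <- ontology(types = w$ontology$types)
  sg <- build_schema_graph(w$db, o, lex = w$lexicon)
  concepts <- sg$nodes$label[sg$nodes$kind == "concept"]
  expect_true(all(concepts %in% sg$backward$concepts$name))
  expect_gt(length(concepts), 0L)
})

test_that("non-key columns reach their key column within one hop (random worlds)", {
  for (seed in c(2, 9, 17, 23, 31)) {
    w <- random_world(seed, n_relations = 4L, n_concepts = 4L)
    sg <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon)
    for (sc in w$db$schemas) {
      for (att in setdiff(sc$attributes, sc$key)) {
        nbr <- igraph::neighbors(sg$graph, paste0("attr:", sc$name, ".", att))$name
        expect_true(any(paste0("attr:", sc$name, ".", sc$key) %in% nbr),
                    info = paste(seed, sc$name, att))
      }
    }
  }
})

test_that("a function whose output names no concept is a construction error", {
  w <- delta_world()
  bad <- register_function(
    function_registry(),
    registry_function("Mystery", inputs = "gene", output = "no-such-concept",
                      fn = function(args) NA_character_))
  expect_error(build_schema_graph(w$db, w$ontology, bad, w$lexicon),
               class = "coopquery_construction_error")
})

test_that("graph exports and summaries are produced", {
  sg <- delta_graph()
  dot <- withr::local_tempfile(fileext = ".dot")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_dot(sg, dot)
  write_graph_graphml(sg, gml)
  expect_true(file.size(dot) > 0 && file.size(gml) > 0)
  expect_match(readLines(dot)[1], "graph")
  g <- glance(sg)
  expect_equal(g$n_unmapped_concepts, 0L)
  expect_equal(g$n_functions, 5L)
  td <- tidy(sg)
  expect_true(all(c("id", "kind", "label") %in% names(td)))
  p <- ggplot2::ggplot_build(autoplot(sg))
  expect_gt(nrow(p$data[[2]]), 0L)
})
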