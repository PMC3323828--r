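printed_path <- c("concept:gene", "attr:Gene.GeneID", "attr:Gene.UniProtID",
                  "concept:protein", "attr:Protein.ProteinID",
                  "attr:Protein.Function")

test_that("the worked query connects along the expected six-node path", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all growth control genes", w$lexicon), sg)
  lqg <- connect_matches(m, sg)
  expect_setequal(lqg$nodes, printed_path)
  # the edges form a simple chain in exactly the printed order
  chain <- lqg$edges
  expect_equal(nrow(chain), 5L)
  walk <- chain$from[1]
  expect_equal(chain$from, printed_path[-6])
  expect_equal(chain$to, printed_path[-1])
  expect_equal(lqg$projections, "Gene.GeneID")
})

test_that("a single-terminal query yields a one-node graph projecting the key", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all genes", w$lexicon), sg)
  lqg <- connect_matches(m, sg)
  expect_equal(lqg$nodes, "concept:gene")
  expect_equal(nrow(lqg$edges), 0L)
  expect_equal(lqg$projections, "Gene.GeneID")
})

test_that("deterministic shortest paths agree with a breadth-first oracle", {
  for (seed in c(1, 4, 8, 15, 16, 23)) {
    set.seed(seed)
    n <- sample(8:25, 1L)
    g <- igraph::sample_gnp(n, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
    comp <- igraph::components(g)
    keep <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    g <- igraph::induced_subgraph(g, keep)
    edges <- igraph::as_data_frame(g)
    vs <- igraph::V(g)$name
    for (rep in 1:10) {
      pick <- sample(vs, 2L)
      sp <- coopquery:::sg_shortest_path(g, pick[1], pick[2])
      expect_equal(sp$dist, bfs_distance(edges, pick[1], pick[2]),
                   info = paste(seed, rep))
      # returned route is an actual path of that length
      expect_equal(length(sp$path) - 1L, sp$dist)
    }
  }
})

test_that("equal-length paths break ties lexicographically and reproducibly", {
  # diamond: a-b-d and a-c-d are both length 2; the b route sorts first
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b", "c"), to = c("b", "c", "d", "d")),
    directed = FALSE)
  sp1 <- coopquery:::sg_shortest_path(g, "a", "d")
  expect_equal(sp1$path, c("a", "b", "d"))
  expect_identical(sp1, coopquery:::sg_shortest_path(g, "a", "d"))
})

test_that("the connected subgraph is minimal: no strict subgraph spans the terminals", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all growth control genes in dogs",
                               w$lexicon), sg)
  lqg <- connect_matches(m, sg)
  terms <- intersect(lqg$terminals$node, lqg$nodes)
  non_terminals <- setdiff(lqg$nodes, terms)
  edges <- lqg$edges
  connected_spanning <- function(nodes) {
    sub <- edges[edges$from %in% nodes & edges$to %in% nodes, ]
    g <- igraph::graph_from_data_frame(sub[, c("from", "to")], directed = FALSE,
                                       vertices = data.frame(name = nodes))
    comp <- igraph::components(g)$membership
    length(unique(comp[terms])) == 1L
  }
  # exhaustively drop every non-empty subset of non-terminal nodes
  for (k in seq_along(non_terminals)) {
    for (drop in utils::combn(non_terminals, k, simplify = FALSE)) {
      expect_false(connected_spanning(setdiff(lqg$nodes, drop)),
                   info = paste(drop, collapse = ","))
    }
  }
})

test_that("terminals in disconnected components reject the query with diagnostics", {
  iw <- island_world()
  sg <- build_schema_graph(iw$db, iw$ontology, iw$registry, iw$lexicon)
  m <- match_terms(parse_query("list all c1 c2s", iw$lexicon), sg)
  err <- expect_error(connect_matches(m, sg),
                      class = "coopquery_disconnected_error")
  expect_match(conditionMessage(err), "stranded")
  expect_true(length(err$stranded) >= 1L)
})

test_that("selection constraints attach to anchored columns verbatim", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all growth control genes in dogs",
                               w$lexicon), sg)
  lqg <- attach_constraints(connect_matches(m, sg), m)
  expect_equal(nrow(lqg$selections), 2L)
  expect_true(all(c("Gene.Organism", "Protein.Function") %in% lqg$selections$ref))
  expect_equal(lqg$selections$value[lqg$selections$ref == "Gene.Organism"], "Dog")
  expect_equal(lqg$selections$value[lqg$selections$ref == "Protein.Function"],
               "growth control")
})

test_that("a query without literals leaves the graph unchanged", {
  sg <- delta_graph()
  w <- delta_world()
  m <- match_terms(parse_query("List all genes", w$lexicon), sg)
  lqg <- connect_matches(m, sg)
  lqg2 <- attach_constraints(lqg, m)
  expect_equal(lqg2$selections, lqg$selections)
  expect_equal(lqg2$nodes, lqg$nodes)
})
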