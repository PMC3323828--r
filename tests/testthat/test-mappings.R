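test_that("concept mapping reproduces the expected attribute census", {
  sg <- delta_graph()
  mu <- sg$cmap$mu
  gene <- mu[mu$concept == "gene", ]
  expect_setequal(gene$attrs[[1]],
                  c("Gene.GeneID", "EquivalentGenes.Object1",
                    "GeneProteinEncoding.Gene"))
  expect_equal(gene$flavor, "entity")
  expect_equal(gene$entity_relation, "Gene")
  protein <- mu[mu$concept == "protein", ]
  expect_setequal(protein$attrs[[1]],
                  c("Protein.ProteinID", "Gene.UniProtID",
                    "GeneProteinEncoding.Protein"))
  expect_equal(mu$flavor[mu$concept == "organism"], "property")
  expect_equal(mu$flavor[mu$concept == "function"], "property")
})

test_that("a column never belongs to two concepts (injectivity)", {
  at <- delta_graph()$cmap$attrs
  mapped <- at[at$role %in% "mapped" & !is.na(at$concept), ]
  expect_equal(anyDuplicated(mapped$ref), 0L)
  # the second prime gene column of the equivalence relation is a partner,
  # not a second mapping
  expect_equal(at$role[at$ref == "EquivalentGenes.Object2"], "partner")
  expect_equal(at$role[at$ref == "Gene.GeneName"], "demoted")
})

test_that("relationship mappings realize both key-key and key-property cases", {
  rmap <- delta_graph()$rmap
  row <- function(a) rmap[rmap$association == a, ]
  expect_equal(row("alias")$ref_a, "EquivalentGenes.Object1")
  expect_equal(row("alias")$ref_b, "EquivalentGenes.Object2")
  expect_equal(row("alias")$category, "key-key")
  expect_equal(row("encode")$ref_a, "GeneProteinEncoding.Gene")
  expect_equal(row("encode")$ref_b, "GeneProteinEncoding.Protein")
  expect_equal(row("partof")$ref_a, "Gene.GeneID")
  expect_equal(row("partof")$ref_b, "Gene.Organism")
  expect_equal(row("partof")$category, "key-property")
  expect_equal(row("function")$ref_a, "Protein.ProteinID")
  expect_equal(row("function")$ref_b, "Protein.Function")
  # gene and function share no relation, so has stays (recorded) unmapped
  expect_equal(row("has")$category, "unmapped")
})

test_that("value concepts map to instance values with polymorphic anchors", {
  vmap <- delta_graph()$vmap
  ortho <- vmap[vmap$concept == "ortholog", ]
  expect_equal(ortho$ref, "EquivalentGenes.Relationship")
  expect_equal(ortho$value, "Ortholog")
  expect_equal(ortho$anchor_kind, "relationship")
  expect_equal(ortho$anchor_a, "EquivalentGenes.Object1")
  expect_equal(ortho$anchor_b, "EquivalentGenes.Object2")
  # homolog appears nowhere in the instance: function-resolvable only
  expect_equal(vmap$anchor_kind[vmap$concept == "homolog"], "none")
})

test_that("backward mapping derives concepts for uncovered columns", {
  back <- delta_graph()$backward
  expect_setequal(back$concepts$name,
                  c("genename", "dnasequence", "proteinname", "relationship"))
  pe <- back$property_edges
  expect_true(any(pe$from_ref == "Gene.GeneName" & pe$to_ref == "Gene.GeneID"))
  expect_true(any(pe$from_ref == "Gene.DNASequence" & pe$to_ref == "Gene.GeneID"))
  # composite-key relation: the stored value column attaches to both primes
  expect_setequal(pe$to_ref[pe$from_ref == "EquivalentGenes.Relationship"],
                  c("EquivalentGenes.Object1", "EquivalentGenes.Object2"))
})

test_that("a fully covered database yields no derived concepts", {
  w <- delta_world()
  db <- database(list(relation_schema("Gene", c("GeneID", "Organism"),
                                      key = "GeneID")),
                 list(Gene = tibble::tibble(GeneID = c("1", "2"),
                                            Organism = c("Human", "Dog"))))
  at <- infer_attribute_types(db, w$ontology$types, w$lexicon)
  cm <- build_concept_mapping(w$ontology, at, db)
  back <- backward_map_database(db, cm, w$ontology)
  expect_equal(nrow(back$concepts), 0L)
  expect_equal(nrow(back$property_edges), 0L)
})

test_that("a one-relation one-attribute database with an empty ontology derives one concept", {
  o <- ontology(types = type_hierarchy(list(c("x", "entity"))))
  db <- database(list(relation_schema("R", "A", key = "A")),
                 list(R = tibble::tibble(A = c("x::1", "x::2"))))
  at <- infer_attribute_types(db, o$types, lexicon(tibble::tibble(surface = character())))
  cm <- build_concept_mapping(o, at, db)
  back <- backward_map_database(db, cm, o)
  expect_equal(nrow(back$concepts), 1L)
  expect_equal(nrow(back$property_edges), 0L)
})

test_that("concept-to-attribute injectivity holds across random worlds", {
  for (seed in 1:40) {
    w <- random_world(seed, n_relations = 3L, n_concepts = 3L)
    at <- infer_attribute_types(w$db, w$ontology$types, w$lexicon)
    cm <- build_concept_mapping(w$ontology, at, w$db)
    mapped <- cm$attrs[cm$attrs$role %in% "mapped" & !is.na(cm$attrs$concept), ]
    expect_equal(anyDuplicated(mapped$ref), 0L, info = paste("seed", seed))
    # every attribute of every mu set is unique across concepts
    all_attrs <- unlist(cm$mu$attrs)
    expect_equal(anyDuplicated(all_attrs), 0L, info = paste("seed", seed))
  }
})
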