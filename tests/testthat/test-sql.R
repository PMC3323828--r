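ask_delta <- function(query, max_depth = 2L, world = delta_world(),
                      sg = delta_graph()) {
  ask(world, query, sg = sg, max_depth = max_depth)
}

test_that("the base interpretation compiles to the expected join/selection SQL", {
  a <- ask_delta("List all growth control genes", max_depth = 0L)
  expect_equal(nrow(a$sql$branches), 1L)
  sql <- a$sql$branches$sql[1]
  expect_match(sql, "^select G\\.GeneID from Gene G, Protein P where ")
  expect_match(sql, "G.UniProtID = P.ProteinID", fixed = TRUE)
  expect_match(sql, "P.Function = 'growth control'", fixed = TRUE)
})

test_that("generated SQL agrees with verbatim reference SQL on row sets", {
  w <- delta_world()
  a <- ask_delta("List all growth control genes", max_depth = 0L)
  reference <- paste(
    "select GeneID from Gene G, Protein P",
    "where G.UniProtID = P.ProteinID and P.Function = \"growth control\"")
  ref_rows <- run_sql(reference, w$db)
  expect_setequal(a$rows[[1]], ref_rows[[1]])
  expect_setequal(ref_rows[[1]], c("55245", "LOC608882"))
})

test_that("the in-package evaluator matches a sqlite3 oracle on plain SQL", {
  w <- delta_world()
  queries <- c(
    "select GeneID from Gene G, Protein P where G.UniProtID = P.ProteinID and P.Function = 'growth control'",
    "select GeneID from Gene G, Protein P where G.UniProtID = P.ProteinID and G.Organism = 'Dog' and P.Function = 'growth control'",
    "select Object2 from EquivalentGenes E where E.Relationship = 'Ortholog'",
    "select GeneID from Gene G where G.Organism = 'Fly'")
  for (q in queries) {
    mine <- sort(run_sql(q, w$db)[[1]])
    oracle <- sqlite_oracle(w$db, q)
    expect_equal(mine, oracle, info = q)
  }
})

test_that("every generated branch parses under the dialect grammar and round-trips", {
  w <- delta_world()
  a <- ask_delta("List all growth control genes in dogs")
  for (i in seq_len(nrow(a$sql$branches))) {
    b <- a$sql$branches[i, ]
    reparsed <- parse_sql(b$sql, w$db)
    direct <- coopquery:::eval_branch(w$db, w$registry, b$tables[[1]],
                                      b$conjuncts[[1]], b$select)
    via_text <- coopquery:::eval_branch(w$db, w$registry,
                                        reparsed$branches$tables[[1]],
                                        reparsed$branches$conjuncts[[1]],
                                        reparsed$branches$select[1])
    expect_setequal(direct[[1]], via_text[[1]])
  }
})

test_that("generated statements are read-only SELECT/UNION forms", {
  a <- ask_delta("List all growth control genes in dogs")
  expect_true(sql_is_read_only(a$sql$text))
  e <- ask_delta("Does gene 55245 encode a protein")
  expect_true(sql_is_read_only(e$sql$text))
  expect_false(sql_is_read_only("drop table Gene"))
  expect_false(sql_is_read_only("select 1; delete from Gene"))
  expect_error(parse_sql("update Gene set Organism = 'Cat'", delta_world()$db),
               class = "coopquery_sql_parse_error")
})

test_that("duplicating a derivation never changes the result (union idempotence)", {
  w <- delta_world()
  a <- ask_delta("List all growth control genes in dogs")
  doubled <- a$sql
  doubled$branches <- dplyr::bind_rows(doubled$branches, doubled$branches)
  r1 <- execute_sql(a$sql, w$db, w$registry)
  r2 <- execute_sql(doubled, w$db, w$registry)
  expect_equal(r1[[1]], r2[[1]])
})

test_that("selections matching nothing give an empty result, not an error", {
  a <- ask_delta("List all growth control genes in plants")
  expect_equal(nrow(a$rows), 0L)
})

test_that("existential questions verify against the stored encoding", {
  w <- delta_world()
  yes <- ask_delta("Does gene 55245 encode a protein")
  expect_true(yes$rows$answer)
  expect_match(yes$sql$text, "^select exists")

  # remove the encoding row: the same question must come back false
  db2 <- w$db
  db2$tables$GeneProteinEncoding <-
    db2$tables$GeneProteinEncoding[db2$tables$GeneProteinEncoding$Gene != "55245", ]
  no <- ask(db2, "Does gene 55245 encode a protein", ontology = w$ontology,
            lexicon = w$lexicon, registry = w$registry)
  expect_false(no$rows$answer)
})

test_that("render_existential refuses non-SQL input", {
  expect_error(render_existential(list()), class = "coopquery_contract_error")
})

test_that("scalar function calls evaluate inside WHERE", {
  w <- delta_world()
  sql <- parse_sql(paste(
    "select GeneID from Gene G, Protein P, EquivalentGenes E",
    "where G.UniProtID = P.ProteinID and G.GeneID = E.Object1",
    "and P.Function = 'growth control' and OrganismMapper(E.Object2) = 'Dog'"),
    w$db)
  rows <- execute_sql(sql, w$db, w$registry)
  expect_equal(rows$GeneID, "55245")
})
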