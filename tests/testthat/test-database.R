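test_that("schema declarations are validated", {
  expect_error(relation_schema("R", c("A", "A"), key = "A"),
               class = "coopquery_schema_error")
  expect_error(relation_schema("R", c("A", "B"), key = "Z"),
               class = "coopquery_schema_error")
  expect_error(relation_schema("R", c("A", "B"), key = character()),
               class = "coopquery_schema_error")
})

test_that("instances violating the declared key are rejected", {
  expect_error(
    database(list(relation_schema("R", c("A", "B"), key = "A")),
             list(R = tibble::tibble(A = c("1", "1"), B = c("x", "y")))),
    class = "coopquery_schema_error")
})

test_that("DDL + CSV round trip reproduces the in-memory database", {
  w <- delta_world()
  dir <- withr::local_tempdir()
  write_database(w$db, file.path(dir, "schema.sql"), dir)
  db2 <- read_database(file.path(dir, "schema.sql"), dir)
  expect_equal(names(db2$schemas), names(w$db$schemas))
  for (nm in names(db2$schemas)) {
    expect_equal(db2$schemas[[nm]]$attributes, w$db$schemas[[nm]]$attributes)
    expect_equal(db2$schemas[[nm]]$key, w$db$schemas[[nm]]$key)
    expect_equal(db2$tables[[nm]], w$db$tables[[nm]])
  }
})

test_that("DDL parser handles inline and trailing PRIMARY KEY forms", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "-- two tables",
    "CREATE TABLE T1 (Id TEXT PRIMARY KEY, Val TEXT);",
    "create table T2 (A TEXT, B TEXT, PRIMARY KEY (A, B));"),
    file.path(dir, "s.sql"))
  write.csv(data.frame(Id = "1", Val = "x"), file.path(dir, "T1.csv"),
            row.names = FALSE)
  write.csv(data.frame(A = "1", B = "2"), file.path(dir, "T2.csv"),
            row.names = FALSE)
  db <- read_database(file.path(dir, "s.sql"), dir)
  expect_equal(db$schemas$T1$key, "Id")
  expect_equal(db$schemas$T2$key, c("A", "B"))
})

test_that("the bundled fixture files load into the same world", {
  dir <- system.file("extdata", "delta", package = "coopquery")
  db <- read_database(file.path(dir, "schema.sql"), dir)
  w <- delta_world()
  expect_equal(db$tables, w$db$tables)
  lex <- read_lexicon(file.path(dir, "lexicon.tsv"))
  expect_equal(nrow(lex), nrow(w$lexicon))
  reg <- read_registry(file.path(dir, "registry.json"))
  expect_equal(call_function(reg, "OrganismMapper", "LOC608882"), "Dog")
  expect_equal(call_function(reg, "IDMapper", "UQCC", "LOC608882"), "Ortholog")
})
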