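#' Declare a relation schema
#'
#' @param name relation name.
#' @param attributes ordered character vector of attribute names.
#' @param key character vector naming the primary-key attributes (must be a
#'   non-empty subset of `attributes`).
#' @return an object of class `coop_relation_schema`.
#' @export
relation_schema <- function(name, attributes, key) {
  if (anyDuplicated(attributes) > 0L) {
    stop_coop(paste0("duplicate attribute names in relation '", name, "'"),
              "schema_error")
  }
  if (length(key) == 0L || !all(key %in% attributes)) {
    stop_coop(paste0("primary key of '", name,
                     "' must be a non-empty subset of its attributes"),
              "schema_error")
  }
  structure(list(name = name, attributes = attributes, key = key),
            class = "coop_relation_schema")
}

#' Assemble an in-memory relational database
#'
#' The instance is held as one tibble per relation with all columns read
#' as character (identifiers, names, sequences); third normal form with
#' declared keys is assumed, matching how the schema-graph construction
#' interprets prime attributes.
#'
#' @param schemas list of [relation_schema()] objects.
#' @param tables named list of data frames, one per relation, columns
#'   matching the declared attributes.
#' @return an object of class `coop_database`.
#' @export
database <- function(schemas, tables) {
  names(schemas) <- map_chr(schemas, "name")
  tables <- tables[names(schemas)]
  for (nm in names(schemas)) {
    sc <- schemas[[nm]]
    tb <- tables[[nm]]
    if (is.null(tb)) stop_coop(paste0("no rows supplied for relation '", nm, "'"),
                               "schema_error")
    if (!identical(names(tb), sc$attributes)) {
      stop_coop(paste0("columns of '", nm, "' do not match its declared attributes"),
                "schema_error")
    }
    tb <- as_tibble(tb)
    tb[] <- lapply(tb, as.character)
    if (nrow(tb) > 0L) {
      kv <- do.call(paste, c(tb[sc$key], sep = "\r"))
      if (anyDuplicated(kv) > 0L) {
        stop_coop(paste0("declared key of '", nm, "' is not unique in the instance"),
                  "schema_error")
      }
    }
    tables[[nm]] <- tb
  }
  structure(list(schemas = schemas, tables = tables), class = "coop_database")
}

#' @export
print.coop_database <- function(x, ...) {
  cat("<coop_database> ", length(x$schemas), " relations\n", sep = "")
  for (sc in x$schemas) {
    cat("  ", sc$name, "(", paste(
      ifelse(sc$attributes %in% sc$key, paste0("*", sc$attributes), sc$attributes),
      collapse = ", "), ")  [", nrow(x$tables[[sc$name]]), " rows]\n", sep = "")
  }
  invisible(x)
}

# all attribute refs as a tibble: relation, attribute, ref ("rel.attr"), prime
attribute_refs <- function(db) {
  bind_rows(map(db$schemas, function(sc) {
    tibble(relation = sc$name, attribute = sc$attributes,
           ref = paste0(sc$name, ".", sc$attributes),
           prime = sc$attributes %in% sc$key)
  }))
}

split_ref <- function(ref) {
  parts <- strsplit(ref, ".", fixed = TRUE)[[1]]
  list(relation = parts[1], attribute = paste(parts[-1], collapse = "."))
}

#' Read a database from SQL DDL plus CSV files
#'
#' Parses a restricted `CREATE TABLE` dialect: one statement per table,
#' column definitions `name TYPE` with an optional inline `PRIMARY KEY`
#' marker or a trailing `PRIMARY KEY (a, b)` clause.  Rows are read from
#' `<data_dir>/<Table>.csv` (header row, all columns as character).
#'
#' @param ddl_path path to the `.sql` schema file.
#' @param data_dir directory holding one CSV per relation.
#' @return a [database()].
#' @export
read_database <- function(ddl_path, data_dir) {
  if (!file.exists(ddl_path)) {
    stop_coop(paste0("DDL file not found: ", ddl_path), "io_error")
  }
  sql <- paste(readLines(ddl_path, warn = FALSE), collapse = "\n")
  sql <- gsub("--[^\n]*", "", sql)
  stmts <- str_trim(strsplit(sql, ";", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  schemas <- list()
  for (st in stmts) {
    m <- regmatches(st, regexec(
      "(?is)^create\\s+table\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\((.*)\\)\\s*$",
      st, perl = TRUE))[[1]]
    if (length(m) == 0L) {
      stop_coop(paste0("cannot parse DDL statement: ", substr(st, 1, 60)),
                "parse_error")
    }
    tab <- m[2]
    body <- m[3]
    items <- str_trim(strsplit(body, ",(?![^()]*\\))", perl = TRUE)[[1]])
    attrs <- character(); key <- character()
    for (it in items) {
      pk <- regmatches(it, regexec("(?i)^primary\\s+key\\s*\\(([^)]*)\\)$",
                                   it, perl = TRUE))[[1]]
      if (length(pk) > 0L) {
        key <- c(key, str_trim(strsplit(pk[2], ",", fixed = TRUE)[[1]]))
        next
      }
      cm <- regmatches(it, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\b(.*)$", it))[[1]]
      attrs <- c(attrs, cm[2])
      if (grepl("(?i)primary\\s+key", cm[3], perl = TRUE)) key <- c(key, cm[2])
    }
    schemas[[tab]] <- relation_schema(tab, attrs, key)
  }
  tables <- map(schemas, function(sc) {
    csv <- file.path(data_dir, paste0(sc$name, ".csv"))
    if (!file.exists(csv)) {
      stop_coop(paste0("missing data file: ", csv), "io_error")
    }
    tb <- utils::read.csv(csv, colClasses = "character", check.names = FALSE)
    as_tibble(tb)
  })
  database(schemas, tables)
}

#' Write a database as SQL DDL plus CSV files
#'
#' @param db a [database()].
#' @param ddl_path output path for the schema file.
#' @param data_dir output directory for one CSV per relation (created if
#'   missing).
#' @return `ddl_path`, invisibly.
#' @export
write_database <- function(db, ddl_path, data_dir) {
  dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
  ddl <- map_chr(db$schemas, function(sc) {
    cols <- paste0("  ", sc$attributes, " TEXT")
    pk <- paste0("  PRIMARY KEY (", paste(sc$key, collapse = ", "), ")")
    paste0("CREATE TABLE ", sc$name, " (\n",
           paste(c(cols, pk), collapse = ",\n"), "\n);")
  })
  writeLines(paste(ddl, collapse = "\n\n"), ddl_path)
  for (nm in names(db$tables)) {
    utils::write.csv(db$tables[[nm]],
                     file.path(data_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(ddl_path)
}
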