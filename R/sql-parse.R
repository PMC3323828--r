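# split a string on a separator, ignoring separators inside quotes
split_outside_quotes <- function(text, sep_regex) {
  chars <- strsplit(text, "")[[1]]
  inq <- FALSE; qch <- ""
  masked <- chars
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (!inq && ch %in% c("'", '"')) { inq <- TRUE; qch <- ch }
    else if (inq && ch == qch) inq <- FALSE
    else if (inq) masked[i] <- ""
  }
  masked_text <- paste(masked, collapse = "")
  starts <- gregexpr(sep_regex, masked_text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (starts[1L] == -1L) return(text)
  lens <- attr(starts, "match.length")
  out <- character(); prev <- 1L
  for (k in seq_along(starts)) {
    out <- c(out, substr(text, prev, starts[k] - 1L))
    prev <- starts[k] + lens[k]
  }
  c(out, substr(text, prev, nchar(text)))
}

strip_quotes <- function(x) {
  x <- str_trim(x)
  if (grepl("^'.*'$", x) || grepl('^".*"$', x)) {
    return(substr(x, 2L, nchar(x) - 1L))
  }
  x
}

is_sql_literal <- function(x) {
  x <- str_trim(x)
  grepl("^'.*'$", x) || grepl('^".*"$', x) || grepl("^[0-9.]+$", x)
}

# Parse one term of the restricted dialect: Alias.Attr, bare Attr
# (resolved against the FROM list), or Fn(arg, ...)
parse_sql_term <- function(txt, tables, db) {
  txt <- str_trim(txt)
  fnm <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*\\((.*)\\)$", txt))[[1]]
  if (length(fnm) > 0L) {
    args <- map(str_trim(strsplit(fnm[3], ",", fixed = TRUE)[[1]]), function(a) {
      if (is_sql_literal(a)) fn_arg_lit(strip_quotes(a))
      else fn_arg_col(resolve_sql_col(a, tables, db))
    })
    return(list(kind = "fn", fn = fnm[2], args = args))
  }
  if (is_sql_literal(txt)) return(list(kind = "lit", value = strip_quotes(txt)))
  list(kind = "col", col = resolve_sql_col(txt, tables, db))
}

resolve_sql_col <- function(txt, tables, db) {
  txt <- str_trim(txt)
  if (grepl(".", txt, fixed = TRUE)) {
    parts <- strsplit(txt, ".", fixed = TRUE)[[1]]
    if (!parts[1] %in% tables$alias) {
      stop_coop(paste0("unknown table alias '", parts[1], "' in SQL"),
                "sql_parse_error")
    }
    return(txt)
  }
  # bare column: find the unique FROM relation declaring it
  owners <- tables$alias[map_lgl(tables$relation, function(r)
    txt %in% db$schemas[[r]]$attributes)]
  if (length(owners) == 0L) {
    stop_coop(paste0("column '", txt, "' not found in any FROM relation"),
              "sql_parse_error")
  }
  if (length(owners) > 1L) {
    stop_coop(paste0("column '", txt, "' is ambiguous in the FROM list"),
              "sql_parse_error")
  }
  paste0(owners[1L], ".", txt)
}

#' Parse a restricted SQL text into executable branch structures
#'
#' Covers the dialect the generator emits (and the style of queries the
#' method's worked examples print): `SELECT` column lists, comma-`FROM`
#' lists with aliases, `WHERE` conjunctions of equality predicates
#' between columns, between a column and a literal, or between a scalar
#' function call and a literal, combined with `UNION`.  Double- or
#' single-quoted string literals are accepted.  Anything else (updates,
#' subqueries, disjunction) is rejected — the evaluator is read-only by
#' construction.
#'
#' @param text SQL text.
#' @param db the [database()] the query refers to (for resolving bare
#'   column names).
#' @return a `coop_sql` object ready for [execute_sql()].
#' @export
parse_sql <- function(text, db) {
  text <- str_trim(gsub("\\s+", " ", text))
  if (!grepl("^select\\b", text, ignore.case = TRUE)) {
    stop_coop("only SELECT statements are supported", "sql_parse_error")
  }
  branch_texts <- split_outside_quotes(text, "\\bunion\\b")
  branches <- list()
  for (bt in branch_texts) {
    m <- regmatches(bt, regexec(
      "(?i)^\\s*select\\s+(.*?)\\s+from\\s+(.*?)(?:\\s+where\\s+(.*))?\\s*$",
      bt, perl = TRUE))[[1]]
    if (length(m) == 0L) {
      stop_coop(paste0("cannot parse SQL branch: ", substr(bt, 1, 80)),
                "sql_parse_error")
    }
    from_items <- str_trim(strsplit(m[3], ",", fixed = TRUE)[[1]])
    tables <- bind_rows(map(from_items, function(it) {
      parts <- strsplit(it, "\\s+")[[1]]
      rel <- parts[1]
      if (!rel %in% names(db$schemas)) {
        stop_coop(paste0("unknown relation '", rel, "' in FROM"),
                  "sql_parse_error")
      }
      tibble(alias = if (length(parts) > 1L) parts[2] else rel, relation = rel)
    }))
    select <- resolve_sql_col(str_trim(m[2]), tables, db)
    conjuncts <- list()
    if (!is.na(m[4]) && nzchar(str_trim(m[4]))) {
      for (cstr in str_trim(split_outside_quotes(m[4], "\\band\\b"))) {
        nn <- regmatches(cstr, regexec("(?i)^(.*)\\s+is\\s+not\\s+null$",
                                       cstr, perl = TRUE))[[1]]
        if (length(nn) > 0L) {
          lhs <- parse_sql_term(nn[2], tables, db)
          if (lhs$kind != "fn") {
            stop_coop("IS NOT NULL is only supported on function calls",
                      "sql_parse_error")
          }
          conjuncts <- c(conjuncts, list(cj_fn(lhs$fn, lhs$args)))
          next
        }
        sides <- str_trim(split_outside_quotes(cstr, "="))
        if (length(sides) != 2L) {
          stop_coop(paste0("cannot parse condition: ", cstr), "sql_parse_error")
        }
        lhs <- parse_sql_term(sides[1], tables, db)
        rhs <- parse_sql_term(sides[2], tables, db)
        cj <- if (lhs$kind == "fn") {
          if (rhs$kind != "lit") stop_coop("function must compare to a literal",
                                           "sql_parse_error")
          cj_fn(lhs$fn, lhs$args, value = rhs$value)
        } else if (lhs$kind == "col" && rhs$kind == "col") {
          list(type = "col_eq", a = lhs$col, b = rhs$col)
        } else if (lhs$kind == "col" && rhs$kind == "lit") {
          cj_lit(lhs$col, rhs$value)
        } else if (lhs$kind == "lit" && rhs$kind == "col") {
          cj_lit(rhs$col, lhs$value)
        } else {
          stop_coop(paste0("unsupported condition: ", cstr), "sql_parse_error")
        }
        conjuncts <- c(conjuncts, list(cj))
      }
    }
    branches[[length(branches) + 1L]] <- tibble(
      derivation_id = paste0("verbatim", length(branches) + 1L),
      select = select, sql = str_trim(bt),
      tables = list(tables), conjuncts = list(conjuncts))
  }
  br <- bind_rows(branches)
  br$branch_id <- paste0("b", seq_len(nrow(br)))
  structure(list(branches = br, text = text, existential = FALSE,
                 projection = NA_character_),
            class = "coop_sql")
}

#' Run a verbatim SQL string against a database
#'
#' Convenience wrapper: [parse_sql()] then [execute_sql()].
#'
#' @param text SQL text in the restricted dialect.
#' @param db a [database()].
#' @param registry functions referenced by the query; defaults to an
#'   empty registry.
#' @return a tibble of distinct result rows (with provenance per branch).
#' @export
run_sql <- function(text, db, registry = function_registry()) {
  execute_sql(parse_sql(text, db), db, registry)
}

#' Check that a SQL text is a read-only SELECT/UNION statement
#'
#' @param text SQL text.
#' @return `TRUE` when every `union`-separated branch is a single SELECT.
#' @export
sql_is_read_only <- function(text) {
  text <- str_trim(gsub("\\s+", " ", text))
  text <- gsub("^select exists \\(", "select", text, ignore.case = TRUE)
  branches <- split_outside_quotes(text, "\\bunion\\b")
  all(grepl("^\\s*select\\b", branches, ignore.case = TRUE)) &&
    !any(grepl("\\b(insert|update|delete|drop|create|alter)\\b",
               branches, ignore.case = TRUE))
}
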