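sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

render_fn_args <- function(args) {
  paste(map_chr(args, function(a) {
    if (a$kind == "lit") sql_quote(a$value) else a$value
  }), collapse = ", ")
}

render_conjunct <- function(cj) {
  switch(cj$type,
    col_eq = paste0(cj$a, " = ", cj$b),
    lit_eq = paste0(cj$a, " = ", sql_quote(cj$value)),
    fn_eq = paste0(cj$fn, "(", render_fn_args(cj$args), ") = ",
                   sql_quote(cj$value)),
    fn_notnull = paste0(cj$fn, "(", render_fn_args(cj$args), ") IS NOT NULL"))
}

render_branch_sql <- function(tables, conjuncts, select) {
  from <- paste(paste(tables$relation, tables$alias), collapse = ", ")
  where <- if (length(conjuncts) > 0L) {
    paste0(" where ", paste(map_chr(conjuncts, render_conjunct),
                            collapse = " and "))
  } else ""
  paste0("select ", select, " from ", from, where)
}

#' Compile derivations into a union SQL query
#'
#' Each derivation's conjunctive form is grounded against the schema
#' graph: traversals within one relation contribute that relation once to
#' FROM, concept crossings between type-compatible columns contribute
#' equality join conjuncts, selection literals become WHERE equalities,
#' and external functions render as scalar calls in WHERE.  Grounding
#' alternatives (stored join vs. registered function) become separate
#' branches; duplicates are removed and the branches are unioned.  The
#' emitted dialect is comma-FROM with single-quoted literals; every
#' statement is a plain SELECT (read-only by construction).
#'
#' Derivations that cannot be grounded (no mapping, no function, or an
#' unsafe variable) are dropped and recorded in `attr(, "ungrounded")`.
#'
#' @param derivations an [expand_derivations()] result.
#' @param sg the schema graph.
#' @param registry a [function_registry()]; defaults to the graph's.
#' @return an object of class `coop_sql`: `branches` (tibble with
#'   `branch_id`, `derivation_id`, `select`, `sql` and structure
#'   list-columns) and `text`, the full union statement.
#' @export
generate_sql <- function(derivations, sg, registry = sg$registry) {
  var_concepts <- attr(derivations, "var_concepts")
  lqg <- attr(derivations, "lqg")
  branches <- list(); ungrounded <- character()
  for (i in seq_len(nrow(derivations))) {
    states <- ground_derivation(derivations$atoms[[i]], sg, registry,
                                var_concepts)
    if (length(states) == 0L) {
      ungrounded <- c(ungrounded, derivations$derivation_id[i])
      next
    }
    for (st in states) {
      select <- st$binds[["X"]][1L]
      sql <- render_branch_sql(st$tables, st$conjuncts, select)
      branches[[length(branches) + 1L]] <- tibble(
        derivation_id = derivations$derivation_id[i],
        select = select, sql = sql,
        tables = list(st$tables), conjuncts = list(st$conjuncts))
    }
  }
  if (length(branches) == 0L) {
    stop_coop("no derivation could be grounded into SQL", "generation_error")
  }
  br <- bind_rows(branches)
  br <- br[!duplicated(br$sql), , drop = FALSE]
  br$branch_id <- paste0("b", seq_len(nrow(br)))
  arity <- map_int(br$select, length)
  if (length(unique(arity)) != 1L) {
    stop_coop("union branches have incompatible select-list arities",
              "generation_error")
  }
  for (cjs in br$conjuncts) {
    for (cj in cjs) {
      if (cj$type %in% c("fn_eq", "fn_notnull") &&
          !cj$fn %in% names(registry$functions)) {
        stop_coop(paste0("branch calls unregistered function '", cj$fn, "'"),
                  "generation_error")
      }
    }
  }
  structure(
    list(branches = br,
         text = paste(br$sql, collapse = "\nunion\n"),
         existential = FALSE,
         projection = lqg$projections %||% NA_character_),
    class = "coop_sql")
}

#' Wrap a query as an existential (yes/no) test
#'
#' "Does ..." / "Is ..." questions are verification queries: the union is
#' evaluated for non-emptiness and a single boolean row is returned.
#'
#' @param sql a [generate_sql()] result.
#' @return the `coop_sql` object with the existential flag set.
#' @export
render_existential <- function(sql) {
  if (!inherits(sql, "coop_sql")) {
    stop_coop("render_existential() expects a generated SQL object",
              "contract_error")
  }
  sql$existential <- TRUE
  sql$text <- paste0("select exists (\n", sql$text, "\n) as answer")
  sql
}

#' @export
print.coop_sql <- function(x, ...) {
  cat("<coop_sql> ", nrow(x$branches), " branch(es)",
      if (x$existential) ", existential", "\n", sep = "")
  cat(x$text, "\n")
  invisible(x)
}

eval_branch <- function(db, registry, tables, conjuncts, select) {
  df <- NULL
  for (i in seq_len(nrow(tables))) {
    tb <- db$tables[[tables$relation[i]]]
    names(tb) <- paste0(tables$alias[i], ".", names(tb))
    df <- if (is.null(df)) tb else dplyr::cross_join(df, tb)
  }
  if (is.null(df)) return(tibble())
  keep <- rep(TRUE, nrow(df))
  for (cj in conjuncts) {
    if (nrow(df) == 0L) break
    ok <- switch(cj$type,
      col_eq = df[[cj$a]] == df[[cj$b]],
      lit_eq = str_to_lower(df[[cj$a]]) == str_to_lower(cj$value),
      {
        vals <- vapply(seq_len(nrow(df)), function(r) {
          args <- map_chr(cj$args, function(a) {
            if (a$kind == "lit") a$value else df[[a$value]][r]
          })
          call_function(registry, cj$fn, args)
        }, character(1))
        if (cj$type == "fn_eq") {
          !is.na(vals) & str_to_lower(vals) == str_to_lower(cj$value)
        } else !is.na(vals)
      })
    ok[is.na(ok)] <- FALSE
    df <- df[ok, , drop = FALSE]
  }
  distinct(df[, select, drop = FALSE])
}

#' Execute a generated union query
#'
#' Branches are evaluated read-only against the in-memory instance with
#' the registry supplying scalar functions; rows are deduplicated across
#' branches and each row carries the set of derivations that produced it
#' (its provenance).  Comparison of string literals is case-insensitive,
#' matching the value-concept match semantics.
#'
#' @param sql a [generate_sql()] (optionally [render_existential()]) result.
#' @param db the [database()] to query.
#' @param registry a [function_registry()].
#' @return for existential queries a one-row tibble `answer = TRUE/FALSE`;
#'   otherwise a tibble with the projected column and a `provenance`
#'   list-column of derivation IDs.
#' @export
execute_sql <- function(sql, db, registry) {
  rows <- list()
  for (i in seq_len(nrow(sql$branches))) {
    b <- sql$branches[i, ]
    res <- eval_branch(db, registry, b$tables[[1L]], b$conjuncts[[1L]],
                       b$select)
    if (nrow(res) == 0L) next
    rows[[length(rows) + 1L]] <- tibble(
      value = res[[1L]], derivation_id = b$derivation_id)
  }
  if (sql$existential) {
    return(tibble(answer = length(rows) > 0L))
  }
  out_name <- col_attr(sql$branches$select[1L])
  if (length(rows) == 0L) {
    out <- tibble(value = character(), provenance = list())
    names(out)[1L] <- out_name
    return(out)
  }
  agg <- bind_rows(rows) |>
    group_by(.data$value) |>
    summarise(provenance = list(sort_c(unique(.data$derivation_id))),
              .groups = "drop") |>
    arrange(.data$value)
  names(agg)[1L] <- out_name
  agg
}
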