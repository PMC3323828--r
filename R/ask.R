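#' Answer an English query over a relational database
#'
#' End-to-end pipeline: parse the query into semantic roles, bind terms
#' to schema-graph nodes, connect them into a logical query graph,
#' cooperatively expand it with the ontology's inference rules and
#' registered external functions, compile the derivations to a union SQL
#' query, and execute it read-only.  "Does/Is" questions are answered
#' existentially (a single boolean).  With `max_depth = 0` only the base
#' (rule-free) interpretation is compiled.
#'
#' @param world a `coop_world` (as from [build_delta()] or
#'   [random_world()]), or a [database()] when the remaining components
#'   are passed explicitly.
#' @param query the English query string.
#' @param ontology,lexicon,registry components used when `world` is a
#'   plain database.
#' @param sg a prebuilt [build_schema_graph()] to reuse; built on the fly
#'   otherwise.
#' @param max_depth maximum rule applications for cooperative expansion.
#' @param sample_size,seed schema-graph construction parameters.
#' @param parser parser backend: a function `(text, lexicon) ->
#'   coop_parsed_query` ([parse_query()] by default, the deterministic
#'   pattern-based fallback).
#' @return an object of class `coop_answer`: `rows` (tibble with
#'   provenance), `sql` (`coop_sql`), `lqg`, `derivations`, `matches`,
#'   `parsed`, `existential`.
#' @examples
#' w <- build_delta()
#' ask(w, "List all growth control genes in dogs")$rows
#' @export
ask <- function(world, query, ontology = NULL, lexicon = NULL,
                registry = NULL, sg = NULL, max_depth = 2L,
                sample_size = 100L, seed = 1L, parser = parse_query) {
  if (inherits(world, "coop_world")) {
    db <- world$db
    ontology <- ontology %||% world$ontology
    lexicon <- lexicon %||% world$lexicon
    registry <- registry %||% world$registry
  } else {
    db <- world
  }
  if (is.null(ontology)) stop_coop("an ontology is required", "usage_error")
  if (is.null(lexicon)) lexicon <- delta_lexicon()[0, ]
  if (is.null(registry)) registry <- function_registry()
  if (is.null(sg)) {
    sg <- build_schema_graph(db, ontology, registry, lexicon,
                             sample_size = sample_size, seed = seed)
  }
  parsed <- parser(query, lexicon)
  matches <- match_terms(parsed, sg)
  lqg <- connect_matches(matches, sg)
  lqg <- attach_constraints(lqg, matches)
  derivations <- expand_derivations(lqg, sg, max_depth = max_depth)
  sql <- generate_sql(derivations, sg, registry)
  existential <- identical(parsed$query_type, "interrogative-existential")
  if (existential) sql <- render_existential(sql)
  rows <- execute_sql(sql, db, registry)
  structure(
    list(rows = rows, sql = sql, lqg = lqg, derivations = derivations,
         matches = matches, parsed = parsed, existential = existential,
         sg = sg),
    class = "coop_answer")
}

#' @export
print.coop_answer <- function(x, ...) {
  cat("<coop_answer> \"", x$parsed$text, "\"\n", sep = "")
  cat("  ", nrow(x$derivations), " derivation(s), ",
      nrow(x$sql$branches), " SQL branch(es)\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' @rdname ask
#' @param x a `coop_answer`.
#' @param ... unused.
#' @method tidy coop_answer
#' @export
tidy.coop_answer <- function(x, ...) {
  out <- x$rows
  if (!x$existential && nrow(out) > 0L) {
    out$provenance <- map_chr(out$provenance, paste, collapse = "+")
  }
  out
}

#' @rdname ask
#' @method glance coop_answer
#' @export
glance.coop_answer <- function(x, ...) {
  tibble(
    query = x$parsed$text,
    query_type = x$parsed$query_type,
    n_rows = nrow(x$rows),
    n_derivations = nrow(x$derivations),
    n_branches = nrow(x$sql$branches),
    existential = x$existential)
}

#' Plot the logical query graph of an answer
#'
#' Terminal nodes (the matched query terms) are highlighted.
#'
#' @param object a `coop_answer` or `coop_query_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coop_answer
#' @export
autoplot.coop_answer <- function(object, ...) {
  autoplot(object$lqg, sg = object$sg, ...)
}

#' @rdname autoplot.coop_answer
#' @param sg the schema graph (for edge metadata); optional.
#' @method autoplot coop_query_graph
#' @export
autoplot.coop_query_graph <- function(object, sg = NULL, ...) {
  nodes <- tibble(id = object$nodes,
                  terminal = object$nodes %in% object$terminals$node)
  n <- nrow(nodes)
  nodes$x <- seq_len(n); nodes$y <- rep(c(0, 1), length.out = n)
  seg <- object$edges |>
    left_join(nodes[, c("id", "x", "y")], by = c(from = "id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes[, c("id", "x", "y")], by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$terminal), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = sub("^[a-z]+:", "", .data$id)),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Logical query graph", colour = "terminal")
}
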