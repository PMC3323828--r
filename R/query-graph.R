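# lexicographic comparison of two node-name vectors
path_lt <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Deterministic Dijkstra from a set of sources.  Ties in distance are
# broken by lexicographic comparison of the node-ID path, so repeated
# runs (and platform changes) give identical routes.  `avoid` removes
# nodes (e.g. function nodes during extensional grounding).
sg_shortest_path <- function(graph, from, to, avoid = character()) {
  vnames <- igraph::V(graph)$name
  keep <- setdiff(vnames, setdiff(avoid, c(from, to)))
  g <- igraph::induced_subgraph(graph, keep)
  vnames <- igraph::V(g)$name
  from <- intersect(from, vnames)
  if (length(from) == 0L || !to %in% vnames) return(NULL)
  dist <- stats::setNames(rep(Inf, length(vnames)), vnames)
  paths <- stats::setNames(vector("list", length(vnames)), vnames)
  done <- stats::setNames(rep(FALSE, length(vnames)), vnames)
  for (s in sort_c(from)) { dist[s] <- 0; paths[[s]] <- s }
  repeat {
    open <- names(dist)[!done & is.finite(dist)]
    if (length(open) == 0L) break
    cur <- open[1L]
    for (cand in open[-1L]) {
      if (dist[cand] < dist[cur] ||
          (dist[cand] == dist[cur] && path_lt(paths[[cand]], paths[[cur]]))) {
        cur <- cand
      }
    }
    if (cur == to) break
    done[cur] <- TRUE
    eids <- igraph::incident(g, cur)
    for (k in seq_along(eids)) {
      e <- eids[k]
      ends <- igraph::ends(g, e)[1L, ]
      nb <- if (ends[1L] == cur) ends[2L] else ends[1L]
      if (done[nb]) next
      w <- igraph::edge_attr(g, "weight", e) %||% 1
      if (is.na(w)) w <- 1
      nd <- dist[cur] + w
      np <- c(paths[[cur]], nb)
      if (nd < dist[nb] || (nd == dist[nb] && path_lt(np, paths[[nb]]))) {
        dist[nb] <- nd
        paths[[nb]] <- np
      }
    }
  }
  if (!is.finite(dist[to])) return(NULL)
  list(dist = unname(dist[to]), path = paths[[to]])
}

# choose one node per candidate group: closest to the primary terminal,
# ties by node ID
resolve_candidates <- function(matches, sg) {
  prim <- matches$node[matches$part == "head"][1L] %or% matches$node[1L]
  resolved <- list()
  for (g in sort(unique(matches$candidate_group))) {
    rows <- matches[matches$candidate_group == g, , drop = FALSE]
    if (nrow(rows) == 1L) { resolved[[length(resolved) + 1L]] <- rows; next }
    d <- suppressWarnings(igraph::distances(sg$graph, v = rows$node, to = prim))
    ord <- order(d[, 1L], rows$node, method = "radix")
    resolved[[length(resolved) + 1L]] <- rows[ord[1L], , drop = FALSE]
  }
  bind_rows(resolved)
}

#' Connect matched terms into a logical query graph
#'
#' The matched nodes are terminals; the connector returns the connected
#' subgraph of the schema graph that grounds the query: for two terminals
#' the minimum-weight path, for more a deterministic Steiner
#' approximation that merges shortest paths in descending match-score
#' order.  All edges weigh 1 except function wiring (weight 2), so
#' stored join paths win over computed ones.  Ties between equal-length
#' paths are broken lexicographically on node IDs.  Terminals falling in
#' different connected components reject the query with a diagnostic
#' naming the stranded terminals — only a connected match is accepted as
#' a logical query graph.
#'
#' The projection is the head noun's entity key column (or the property
#' column itself for property concepts).  Selection predicates are added
#' by [attach_constraints()].
#'
#' @param matches a [match_terms()] result.
#' @param sg the schema graph the matches were made against.
#' @return an object of class `coop_query_graph`: `nodes`, `edges`,
#'   `terminals`, `projections`, `selections`, `head_concept`,
#'   `query_type`.
#' @export
connect_matches <- function(matches, sg) {
  chosen <- resolve_candidates(as_tibble(matches), sg)
  # association matches contribute their mapped column pair as terminals
  assoc_rows <- chosen[startsWith(chosen$node, "assoc:"), , drop = FALSE]
  node_rows <- chosen[!startsWith(chosen$node, "assoc:"), , drop = FALSE]
  assoc_terms <- character()
  for (a in assoc_rows$node) {
    nm <- sub("^assoc:", "", a)
    pair <- filter(sg$rmap, .data$association == nm, .data$category != "unmapped")
    if (nrow(pair) > 0L) {
      assoc_terms <- c(assoc_terms, paste0("attr:", c(pair$ref_a[1L], pair$ref_b[1L])))
    }
  }
  ord <- order(-node_rows$score, node_rows$node, method = "radix")
  terminals <- unique(c(node_rows$node[ord], assoc_terms))
  if (length(terminals) == 0L) {
    stop_coop("no terminal nodes to connect", "no_match_error")
  }
  missing_nodes <- setdiff(terminals, sg$nodes$id)
  if (length(missing_nodes) > 0L) {
    stop_coop(paste0("terminal(s) not present in schema graph: ",
                     paste(missing_nodes, collapse = ", ")), "no_match_error")
  }

  comp <- igraph::components(sg$graph)
  memb <- comp$membership[terminals]
  if (length(unique(memb)) > 1L) {
    main <- as.integer(names(sort(table(memb), decreasing = TRUE))[1L])
    stranded <- terminals[memb != main]
    stop_coop(
      paste0("query terms fall in disconnected parts of the schema graph; ",
             "stranded: ", paste(stranded, collapse = ", ")),
      "disconnected_error", stranded = stranded)
  }

  tree_nodes <- terminals[1L]
  tree_edges <- tibble(from = character(), to = character())
  for (t in terminals[-1L]) {
    if (t %in% tree_nodes) next
    sp <- sg_shortest_path(sg$graph, tree_nodes, t)
    if (is.null(sp)) {
      stop_coop(paste0("no path connects terminal ", t), "disconnected_error",
                stranded = t)
    }
    p <- sp$path
    if (length(p) > 1L) {
      tree_edges <- bind_rows(tree_edges,
                              tibble(from = p[-length(p)], to = p[-1L]))
    }
    tree_nodes <- unique(c(tree_nodes, p))
  }
  edge_info <- NULL
  if (nrow(tree_edges) > 0L) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    se <- mutate(sg$edges, k = key(.data$from, .data$to))
    edge_info <- tree_edges |>
      mutate(k = key(.data$from, .data$to)) |>
      left_join(select(se, "k", "kind", "label"), by = "k",
                relationship = "many-to-many") |>
      distinct(.data$from, .data$to, .keep_all = TRUE) |>
      select(-"k")
  } else {
    edge_info <- tibble(from = character(), to = character(),
                        kind = character(), label = character())
  }

  # projection from the primary head noun
  head_rows <- node_rows[node_rows$part == "head", , drop = FALSE]
  head_node <- head_rows$node[1L] %or% terminals[1L]
  proj <- projection_for(head_node, sg)

  structure(
    list(nodes = sort_c(tree_nodes), edges = edge_info,
         terminals = chosen, head_node = head_node,
         head_concept = sub("^concept:", "", head_node),
         projections = proj,
         selections = tibble(ref = character(), op = character(),
                             value = character()),
         query_type = attr(matches, "parsed")$query_type %||% "imperative"),
    class = "coop_query_graph")
}

projection_for <- function(node, sg) {
  if (startsWith(node, "attr:")) return(sub("^attr:", "", node))
  cc <- sub("^concept:", "", node)
  mu <- sg$cmap$mu
  row <- mu[mu$concept == cc, , drop = FALSE]
  if (nrow(row) == 1L && row$flavor == "entity") {
    sc <- sg$db$schemas[[row$entity_relation]]
    return(paste0(row$entity_relation, ".", sc$key[1L]))
  }
  if (nrow(row) == 1L) return(row$attrs[[1L]][1L])
  # derived or value concept: first column classifying under it
  bk <- sg$backward$concepts
  drow <- bk[bk$name == cc, , drop = FALSE]
  if (nrow(drow) == 1L) return(drow$attrs[[1L]][1L])
  vrow <- filter(sg$vmap, .data$concept == cc, .data$anchor_kind != "none")
  if (nrow(vrow) > 0L) return(vrow$ref[1L])
  stop_coop(paste0("no projectable column for node ", node), "no_match_error")
}

#' Attach selection constraints to a logical query graph
#'
#' Every value-literal terminal becomes an equality selection on its
#' anchored column (the stored capitalization of the value is used, so
#' "dogs" selects `Organism = 'Dog'`); multiword literals are kept
#' verbatim.  A literal whose anchor column is absent from the connected
#' subgraph raises a constraint-anchor error.
#'
#' @param lqg a [connect_matches()] result.
#' @param matches the same matches that produced `lqg`.
#' @return the updated `coop_query_graph`.
#' @export
attach_constraints <- function(lqg, matches) {
  lits <- filter(as_tibble(lqg$terminals), .data$match_kind == "value-literal")
  sels <- list()
  for (i in seq_len(nrow(lits))) {
    ref <- sub("^attr:", "", lits$node[i])
    if (!lits$node[i] %in% lqg$nodes) {
      stop_coop(paste0("selection literal '", lits$literal[i],
                       "' anchors at ", ref, ", which is not on the query path"),
                "constraint_anchor_error")
    }
    sels[[length(sels) + 1L]] <- tibble(ref = ref, op = "=",
                                        value = lits$literal[i])
  }
  if (length(sels) > 0L) {
    lqg$selections <- arrange(distinct(bind_rows(sels)), .data$ref, .data$value)
  }
  lqg
}

#' @export
print.coop_query_graph <- function(x, ...) {
  cat("<coop_query_graph> ", length(x$nodes), " nodes, head '",
      x$head_concept, "', project ", paste(x$projections, collapse = ", "),
      "\n", sep = "")
  if (nrow(x$selections) > 0L) {
    cat("  where ", paste(paste0(x$selections$ref, " = '", x$selections$value, "'"),
                          collapse = " and "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname connect_matches
#' @param x a `coop_query_graph`.
#' @param ... unused.
#' @method tidy coop_query_graph
#' @export
tidy.coop_query_graph <- function(x, ...) {
  tibble(node = x$nodes, terminal = x$nodes %in% x$terminals$node)
}

#' Export a logical query graph to DOT
#' @param lqg a `coop_query_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lqg_dot <- function(lqg, path) {
  quote_id <- function(x) paste0('"', gsub('"', "'", x), '"')
  lines <- c(
    "graph logical_query_graph {",
    paste0("  ", quote_id(lqg$nodes),
           ifelse(lqg$nodes %in% lqg$terminals$node,
                  " [penwidth=2, color=red]", ""), ";"),
    if (nrow(lqg$edges) > 0L)
      paste0("  ", quote_id(lqg$edges$from), " -- ", quote_id(lqg$edges$to),
             ifelse(is.na(lqg$edges$label), "",
                    paste0(" [label=", quote_id(lqg$edges$label), "]")), ";"),
    "}")
  writeLines(lines, path)
  invisible(path)
}
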