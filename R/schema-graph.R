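#' Build the ontology-augmented schema graph
#'
#' Merges an ontology, a database scheme, its instance, and a registry of
#' external functions into one reachability structure.  Nodes are
#' concepts (`concept:<name>`), database columns (`attr:<rel>.<attr>`)
#' and functions (`fn:<name>`).  Edges are classifications (column to its
#' concept), named associations (column pair realizing an ontology
#' association), unnamed properties (non-key column to its relation's key
#' column), and function wiring (input concepts to the function node to
#' its output concept).  Function edges carry weight 2 so that stored
#' join paths are preferred over computed ones when both exist; all other
#' edges weigh 1.
#'
#' Construction is deterministic given identical inputs and `seed` (the
#' seed only affects column-value sampling for type inference).
#'
#' @param db a [database()].
#' @param o a [ontology()].
#' @param registry a [function_registry()] (may be empty).
#' @param lex a [lexicon()] used for value typing and synonym matching.
#' @param sample_size,seed passed to [infer_attribute_types()].
#' @return an object of class `coop_schema_graph`.
#' @export
build_schema_graph <- function(db, o, registry = function_registry(),
                               lex = lexicon(tibble(surface = character())),
                               sample_size = 100L, seed = 1L) {
  attr_types <- infer_attribute_types(db, o$types, lex, sample_size, seed)
  cmap <- build_concept_mapping(o, attr_types, db)
  rmap <- build_relationship_mappings(o, cmap, db)
  vmap <- build_value_mappings(o, cmap, rmap, db, lex)
  back <- backward_map_database(db, cmap, o)

  nodes <- list(); edges <- list()
  add_node <- function(id, kind, label) {
    nodes[[length(nodes) + 1L]] <<- tibble(id = id, kind = kind, label = label)
  }
  add_edge <- function(from, to, kind, label = NA_character_, weight = 1) {
    edges[[length(edges) + 1L]] <<- tibble(from = from, to = to, kind = kind,
                                           label = label, weight = weight)
  }

  for (ref in attribute_refs(db)$ref) add_node(paste0("attr:", ref), "attribute", ref)

  # concept nodes: ontology concepts with a database representation
  mapped_concepts <- cmap$mu$concept %||% character()
  value_concepts <- unique(vmap$concept[vmap$anchor_kind != "none"])
  for (cc in sort_c(unique(c(mapped_concepts, value_concepts)))) {
    add_node(paste0("concept:", cc), "concept", cc)
  }
  for (cc in back$concepts$name) add_node(paste0("concept:", cc), "concept", cc)

  # classification edges for mapped and partner columns
  cls <- filter(cmap$attrs, .data$role %in% c("mapped", "partner"))
  for (i in seq_len(nrow(cls))) {
    add_edge(paste0("attr:", cls$ref[i]), paste0("concept:", cls$concept[i]),
             "classification")
  }
  for (i in seq_len(nrow(back$concepts))) {
    for (ref in back$concepts$attrs[[i]]) {
      add_edge(paste0("attr:", ref), paste0("concept:", back$concepts$name[i]),
               "classification")
    }
  }
  # a value concept classifies the column that stores it
  vhit <- filter(vmap, .data$anchor_kind != "none")
  for (i in seq_len(nrow(vhit))) {
    add_edge(paste0("attr:", vhit$ref[i]), paste0("concept:", vhit$concept[i]),
             "classification")
  }

  # named association edges
  ramp <- filter(rmap, .data$category != "unmapped")
  for (i in seq_len(nrow(ramp))) {
    add_edge(paste0("attr:", ramp$ref_a[i]), paste0("attr:", ramp$ref_b[i]),
             "association", label = ramp$association[i])
  }

  # unnamed property edges: every non-key column to its relation's key
  # column(s), unless a named association already joins that pair
  assoc_pairs <- paste(pmin(ramp$ref_a, ramp$ref_b), pmax(ramp$ref_a, ramp$ref_b))
  for (sc in db$schemas) {
    for (att in setdiff(sc$attributes, sc$key)) {
      ref <- paste0(sc$name, ".", att)
      for (k in sc$key) {
        kref <- paste0(sc$name, ".", k)
        pair <- paste(min(ref, kref), max(ref, kref))
        if (pair %in% assoc_pairs) next
        add_edge(paste0("attr:", ref), paste0("attr:", kref), "property")
      }
    }
  }

  # function nodes: wire inputs -> fn -> output through concept nodes
  node_ids <- map_chr(nodes, function(x) x$id)
  concept_labels <- sub("^concept:", "", grep("^concept:", node_ids, value = TRUE))
  concept_types <- c(
    stats::setNames(o$concepts$type, o$concepts$name),
    stats::setNames(back$concepts$type, back$concepts$name))
  resolve_concept <- function(id) {
    if (id %in% concept_labels) return(id)
    by_type <- sort_c(names(concept_types)[!is.na(concept_types) &
                                             concept_types == id &
                                             names(concept_types) %in% concept_labels])
    if (length(by_type) > 0L) return(by_type[1L])
    NA_character_
  }
  for (fname in sort_c(names(registry$functions))) {
    entry <- registry$functions[[fname]]
    out_c <- resolve_concept(entry$output)
    if (is.na(out_c)) {
      stop_coop(paste0("function '", fname, "' output type '", entry$output,
                       "' names no concept present in the graph"),
                "construction_error")
    }
    add_node(paste0("fn:", fname), "function", fname)
    for (inp in entry$inputs) {
      in_c <- resolve_concept(inp)
      if (is.na(in_c)) next
      add_edge(paste0("concept:", in_c), paste0("fn:", fname), "function", weight = 2)
    }
    add_edge(paste0("fn:", fname), paste0("concept:", out_c), "function", weight = 2)
  }

  nodes <- arrange(distinct(bind_rows(nodes)), .data$id)
  edges <- bind_rows(edges)
  if (nrow(edges) > 0L) {
    edges <- edges |>
      mutate(lo = pmin(.data$from, .data$to), hi = pmax(.data$from, .data$to)) |>
      distinct(.data$lo, .data$hi, .data$kind, .data$label, .keep_all = TRUE) |>
      select(-"lo", -"hi") |>
      arrange(.data$from, .data$to, .data$kind)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = as.data.frame(nodes))

  sg <- structure(
    list(graph = g, nodes = nodes, edges = edges, db = db, ontology = o,
         lexicon = lex, registry = registry, attr_types = attr_types,
         cmap = cmap, rmap = rmap, vmap = vmap, backward = back,
         sample_size = sample_size, seed = seed),
    class = "coop_schema_graph")
  validate_schema_graph(sg)
  sg
}

validate_schema_graph <- function(sg) {
  # injectivity: a column classifies under at most one non-value concept
  cls <- filter(sg$cmap$attrs, .data$role == "mapped")
  if (anyDuplicated(cls$ref) > 0L) {
    stop_coop("schema graph invariant violated: a column maps to two concepts",
              "construction_error")
  }
  # every non-key column reaches its relation's key column in one hop
  for (sc in sg$db$schemas) {
    for (att in setdiff(sc$attributes, sc$key)) {
      ref <- paste0("attr:", sc$name, ".", att)
      nbr <- igraph::neighbors(sg$graph, ref)$name
      krefs <- paste0("attr:", sc$name, ".", sc$key)
      if (!any(krefs %in% nbr)) {
        stop_coop(paste0("schema graph invariant violated: ", ref,
                         " is not adjacent to its relation's key"),
                  "construction_error")
      }
    }
  }
  invisible(sg)
}

#' Construction census of a schema graph
#'
#' Accounts for every ontology concept and association: mapped to
#' columns, value-mapped to instance values, function-resolvable, or
#' explicitly unmapped — nothing is silently dropped.
#'
#' @param sg a [build_schema_graph()] result.
#' @return a list of tibbles and counts, suitable for JSON export.
#' @export
graph_census <- function(sg) {
  o <- sg$ontology
  mapped <- sg$cmap$mu$concept %||% character()
  value_mapped <- unique(sg$vmap$concept[sg$vmap$anchor_kind != "none"])
  fn_only <- unique(sg$vmap$concept[sg$vmap$anchor_kind == "none"])
  unmapped_concepts <- setdiff(o$concepts$name, c(mapped, value_mapped))
  list(
    concepts_mapped = sg$cmap$mu,
    entity_concepts = sort_c(sg$cmap$entity),
    value_mapped_concepts = sort_c(value_mapped),
    function_resolvable_only = sort_c(fn_only),
    unmapped_concepts = sort_c(unmapped_concepts),
    associations_mapped = filter(sg$rmap, .data$category != "unmapped"),
    associations_unmapped = sort_c(
      unique(sg$rmap$association[sg$rmap$category == "unmapped"])),
    derived_concepts = sg$backward$concepts,
    function_nodes = sort_c(names(sg$registry$functions)),
    undefined_predicates = o$undefined_predicates,
    n_nodes = nrow(sg$nodes), n_edges = nrow(sg$edges))
}

#' @export
print.coop_schema_graph <- function(x, ...) {
  cat("<coop_schema_graph> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "concept"), " concepts, ",
      sum(x$nodes$kind == "attribute"), " columns, ",
      sum(x$nodes$kind == "function"), " functions), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname build_schema_graph
#' @param x a `coop_schema_graph`.
#' @param ... unused.
#' @method tidy coop_schema_graph
#' @export
tidy.coop_schema_graph <- function(x, ...) {
  left_join(x$nodes,
            rename(x$cmap$attrs, node_concept = "concept"),
            by = c(label = "ref")) |>
    select("id", "kind", "label", "relation", "attribute", "type",
           "node_concept", "role")
}

#' @rdname build_schema_graph
#' @method glance coop_schema_graph
#' @export
glance.coop_schema_graph <- function(x, ...) {
  cen <- graph_census(x)
  tibble(
    n_nodes = cen$n_nodes, n_edges = cen$n_edges,
    n_concepts_mapped = nrow(cen$concepts_mapped),
    n_entity_concepts = length(cen$entity_concepts),
    n_value_concepts = length(cen$value_mapped_concepts),
    n_unmapped_concepts = length(cen$unmapped_concepts),
    n_associations_mapped = length(unique(cen$associations_mapped$association)),
    n_derived_concepts = nrow(cen$derived_concepts),
    n_functions = length(cen$function_nodes))
}

#' Plot a schema graph
#'
#' Concepts draw as squares, columns as circles, functions as triangles;
#' association edges are labelled.  Layout is a deterministic
#' Fruchterman-Reingold embedding.
#'
#' @param object a `coop_schema_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot coop_schema_graph
#' @export
autoplot.coop_schema_graph <- function(object, ...) {
  g <- object$graph
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(42)
  xy <- igraph::layout_with_fr(g)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  pos <- tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                kind = object$nodes$kind[match(igraph::V(g)$name, object$nodes$id)],
                label = sub("^[a-z]+:", "", igraph::V(g)$name))
  seg <- object$edges |>
    left_join(pos[, c("id", "x", "y")], by = c(from = "id")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(pos[, c("id", "x", "y")], by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   linetype = .data$kind),
      colour = "grey55") +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind,
                   colour = .data$kind), size = 3) +
    ggplot2::geom_text(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -1, size = 2.8) +
    ggplot2::scale_shape_manual(values = c(concept = 15, attribute = 16,
                                           `function` = 17)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Schema graph")
}

#' Export a schema graph to DOT or GraphML
#'
#' @param sg a `coop_schema_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(sg, path) {
  quote_id <- function(x) paste0('"', gsub('"', "'", x), '"')
  shape <- c(concept = "box", attribute = "ellipse", `function` = "ellipse")
  style <- c(concept = "solid", attribute = "solid", `function` = "dashed")
  lines <- c(
    "graph schema_graph {",
    paste0("  ", quote_id(sg$nodes$id), " [shape=", shape[sg$nodes$kind],
           ", style=", style[sg$nodes$kind], "];"),
    paste0("  ", quote_id(sg$edges$from), " -- ", quote_id(sg$edges$to),
           ifelse(is.na(sg$edges$label), "",
                  paste0(" [label=", quote_id(sg$edges$label), "]")), ";"),
    "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph_dot
#' @export
write_graph_graphml <- function(sg, path) {
  igraph::write_graph(sg$graph, path, format = "graphml")
  invisible(path)
}

# lower-case value index used by the term matcher: value -> columns holding it
sg_value_hits <- function(sg, value) {
  hits <- list()
  needle <- str_to_lower(str_trim(value))
  for (rel in names(sg$db$tables)) {
    tb <- sg$db$tables[[rel]]
    for (att in names(tb)) {
      vals <- unique(compact_chr(tb[[att]]))
      hit <- vals[str_to_lower(vals) == needle]
      if (length(hit) > 0L) {
        hits[[length(hits) + 1L]] <- tibble(
          relation = rel, attribute = att, ref = paste0(rel, ".", att),
          stored = sort_c(hit)[1L])
      }
    }
  }
  if (length(hits) == 0L) {
    tibble(relation = character(), attribute = character(),
           ref = character(), stored = character())
  } else {
    arrange(bind_rows(hits), .data$ref)
  }
}
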