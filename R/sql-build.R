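# ---- grounding state -------------------------------------------------------
# A grounding state accumulates table instances (alias -> relation),
# variable bindings (var -> "Alias.Attr" columns; the first binding is the
# representative), and WHERE conjuncts.  Grounding an atom may yield
# several alternative states (e.g. a stored join vs. an external function
# call); the cartesian product over atoms yields the branch set.

new_state <- function() {
  list(tables = tibble(alias = character(), relation = character()),
       binds = list(), conjuncts = list())
}

state_add_table <- function(state, relation) {
  letter <- toupper(substr(relation, 1L, 1L))
  same <- sum(startsWith(state$tables$alias, letter) &
                substr(state$tables$alias, 1L, 1L) == letter)
  alias <- if (same == 0L) letter else paste0(letter, same + 1L)
  state$tables <- bind_rows(state$tables, tibble(alias = alias, relation = relation))
  list(state = state, alias = alias)
}

state_col <- function(alias, attr) paste0(alias, ".", attr)

col_alias <- function(col) sub("\\..*$", "", col)
col_attr <- function(col) sub("^[^.]*\\.", "", col)

# "Alias.Attr" -> "Relation.Attr"
state_col_ref <- function(state, col) {
  rel <- state$tables$relation[state$tables$alias == col_alias(col)]
  paste0(rel, ".", col_attr(col))
}

state_add_conjunct <- function(state, cj) {
  state$conjuncts <- c(state$conjuncts, list(cj))
  state
}

state_bind <- function(state, var, col) {
  cur <- state$binds[[var]]
  if (is.null(cur)) {
    state$binds[[var]] <- col
  } else if (!col %in% cur) {
    state$binds[[var]] <- c(cur, col)
    state <- state_add_conjunct(state, list(type = "col_eq", a = cur[1L], b = col))
  }
  state
}

cj_lit <- function(col, value) list(type = "lit_eq", a = col, value = value)
cj_fn <- function(fn, args, value = NULL) {
  list(type = if (is.null(value)) "fn_notnull" else "fn_eq",
       fn = fn, args = args, value = value)
}
fn_arg_var <- function(v) list(kind = "var", value = v)
fn_arg_col <- function(col) list(kind = "col", value = col)
fn_arg_lit <- function(x) list(kind = "lit", value = x)

# concept carried by a column ("Rel.Attr"), through forward or backward mapping
concept_of_ref <- function(sg, ref) {
  at <- sg$cmap$attrs
  hit <- at$concept[at$ref == ref & at$role %in% c("mapped", "partner")]
  if (length(hit) > 0L && !is.na(hit[1L])) return(hit[1L])
  bk <- sg$backward$concepts
  for (i in seq_len(nrow(bk))) {
    if (ref %in% bk$attrs[[i]]) return(bk$name[i])
  }
  NA_character_
}

var_position <- function(state, sg, var, var_concepts) {
  cols <- state$binds[[var]]
  if (!is.null(cols)) {
    return(list(kind = "col", col = cols[1L],
                node = paste0("attr:", state_col_ref(state, cols[1L]))))
  }
  cc <- unname(var_concepts[var] %or% NA_character_)
  if (is.na(cc)) return(NULL)
  list(kind = "concept", concept = cc, node = paste0("concept:", cc))
}

# walk a schema-graph path, translating it into table instances and join
# conjuncts; returns NULL when no path exists
ground_via_path <- function(state, sg, start, target_ref) {
  fn_nodes <- sg$nodes$id[sg$nodes$kind == "function"]
  sp <- sg_shortest_path(sg$graph, start$node, paste0("attr:", target_ref),
                         avoid = fn_nodes)
  if (is.null(sp)) return(NULL)
  cur_col <- if (start$kind == "col") start$col else NULL
  first_col <- cur_col
  prev_kind <- if (start$kind == "col") "attribute" else "concept"
  for (node in sp$path[-1L]) {
    if (startsWith(node, "concept:")) { prev_kind <- "concept"; next }
    ref <- sub("^attr:", "", node)
    parts <- split_ref(ref)
    if (is.null(cur_col)) {
      at <- state_add_table(state, parts$relation)
      state <- at$state
      cur_col <- state_col(at$alias, parts$attribute)
      if (is.null(first_col)) first_col <- cur_col
    } else if (prev_kind == "attribute") {
      # attribute-to-attribute edges stay inside one relation instance
      cur_col <- state_col(col_alias(cur_col), parts$attribute)
    } else {
      # crossed a concept node: equality join onto a (possibly new) instance
      if (state_col_ref(state, cur_col) == ref) {
        prev_kind <- "attribute"
        next
      }
      at <- state_add_table(state, parts$relation)
      state <- at$state
      new_col <- state_col(at$alias, parts$attribute)
      state <- state_add_conjunct(state, list(type = "col_eq", a = cur_col,
                                              b = new_col))
      cur_col <- new_col
    }
    prev_kind <- "attribute"
  }
  list(state = state, end_col = cur_col, first_col = first_col)
}

# ---- per-atom grounding ----------------------------------------------------

ground_unary <- function(state, sg, a, var_concepts) {
  v <- a$args[1L]; cc <- a$predicate
  cols <- state$binds[[v]]
  if (!is.null(cols)) {
    concepts <- map_chr(cols, function(col) concept_of_ref(sg, state_col_ref(state, col)))
    if (cc %in% concepts) return(list(state))
  }
  mu <- sg$cmap$mu
  murow <- mu[mu$concept == cc, , drop = FALSE]
  if (nrow(murow) == 1L && murow$flavor == "entity") {
    rel <- murow$entity_relation
    at <- state_add_table(state, rel)
    state <- at$state
    col <- state_col(at$alias, sg$db$schemas[[rel]]$key[1L])
    return(list(state_bind(state, v, col)))
  }
  if (nrow(murow) == 1L) {
    ref <- murow$attrs[[1L]][1L]
    parts <- split_ref(ref)
    at <- state_add_table(state, parts$relation)
    state <- at$state
    return(list(state_bind(state, v, state_col(at$alias, parts$attribute))))
  }
  vrow <- filter(sg$vmap, .data$concept == cc, .data$anchor_kind != "none")
  if (nrow(vrow) > 0L) {
    parts <- split_ref(vrow$ref[1L])
    anch <- split_ref(vrow$anchor_a[1L])
    at <- state_add_table(state, parts$relation)
    state <- at$state
    state <- state_add_conjunct(
      state, cj_lit(state_col(at$alias, parts$attribute), vrow$value[1L]))
    return(list(state_bind(state, v, state_col(at$alias, anch$attribute))))
  }
  bk <- sg$backward$concepts
  brow <- bk[bk$name == cc, , drop = FALSE]
  if (nrow(brow) == 1L) {
    parts <- split_ref(brow$attrs[[1L]][1L])
    at <- state_add_table(state, parts$relation)
    state <- at$state
    return(list(state_bind(state, v, state_col(at$alias, parts$attribute))))
  }
  list()
}

# direct grounding of an association atom onto its mapped column pair,
# reusing an existing instance when the subject is already bound to the
# pair's first column (this is what keeps `G.Organism = 'Dog'` on the
# same Gene instance as the rest of the query)
ground_assoc_direct <- function(state, sg, pair, a, var_concepts) {
  v <- a$args[1L]; w <- a$args[2L]; w_lit <- a$lits[2L]
  pa <- split_ref(pair$ref_a); pb <- split_ref(pair$ref_b)
  cols <- state$binds[[v]]
  alias <- NULL
  if (!is.null(cols)) {
    hit <- cols[map_chr(cols, function(col) state_col_ref(state, col)) == pair$ref_a]
    if (length(hit) > 0L) alias <- col_alias(hit[1L])
  }
  if (is.null(alias)) {
    at <- state_add_table(state, pa$relation)
    state <- at$state
    alias <- at$alias
    state <- state_bind(state, v, state_col(alias, pa$attribute))
  }
  wcol <- state_col(alias, pb$attribute)
  if (w_lit) {
    state <- state_add_conjunct(state, cj_lit(wcol, w))
  } else {
    state <- state_bind(state, w, wcol)
  }
  state
}

ground_binary <- function(state, sg, registry, a, var_concepts) {
  v <- a$args[1L]; w <- a$args[2L]
  w_lit <- a$lits[2L]; w_anchor <- a$anchors[2L]
  options <- list()

  # (1) value-mapped predicate (e.g. ortholog stored as a Relationship
  # value): symmetric, so both argument orientations ground
  vrows <- filter(sg$vmap, .data$concept == a$predicate,
                  .data$anchor_kind == "relationship")
  for (i in seq_len(nrow(vrows))) {
    vr <- vrows[i, ]
    parts <- split_ref(vr$ref)
    aa <- split_ref(vr$anchor_a); ab <- split_ref(vr$anchor_b)
    for (orient in list(c(1L, 2L), c(2L, 1L))) {
      st <- state
      at <- state_add_table(st, parts$relation)
      st <- at$state
      st <- state_add_conjunct(st, cj_lit(state_col(at$alias, parts$attribute),
                                          vr$value))
      ends <- list(state_col(at$alias, aa$attribute),
                   state_col(at$alias, ab$attribute))
      vcol <- ends[[orient[1L]]]; wcol <- ends[[orient[2L]]]
      st <- if (a$lits[1L]) state_add_conjunct(st, cj_lit(vcol, v)) else
        state_bind(st, v, vcol)
      st <- if (w_lit) state_add_conjunct(st, cj_lit(wcol, w)) else
        state_bind(st, w, wcol)
      options[[length(options) + 1L]] <- st
    }
  }

  # (2) mapped association: direct pair grounding when the subject's
  # concept matches the pair's first column, else a shortest-path bridge
  arows <- filter(sg$rmap, .data$association == a$predicate,
                  .data$category != "unmapped")
  target_concept <- NA_character_
  if (nrow(arows) > 0L) {
    pair <- arows[1L, ]
    target_concept <- pair$target
    vc <- NA_character_
    cols <- state$binds[[v]]
    if (!is.null(cols)) {
      vc <- concept_of_ref(sg, state_col_ref(state, cols[1L]))
    } else {
      vc <- unname(var_concepts[v] %or% pair$source)
    }
    if (!is.na(vc) && identical(vc, concept_of_ref(sg, pair$ref_a))) {
      options[[length(options) + 1L]] <-
        ground_assoc_direct(state, sg, pair, a, var_concepts)
    } else {
      target_ref <- if (w_lit && !is.na(w_anchor)) w_anchor else pair$ref_b
      start <- var_position(state, sg, v, var_concepts)
      if (!is.null(start)) {
        res <- ground_via_path(state, sg, start, target_ref)
        if (!is.null(res)) {
          st <- res$state
          if (start$kind == "concept" && !is.null(res$first_col)) {
            st <- state_bind(st, v, res$first_col)
          }
          st <- if (w_lit) state_add_conjunct(st, cj_lit(res$end_col, w)) else
            state_bind(st, w, res$end_col)
          options[[length(options) + 1L]] <- st
        }
      }
    }
  } else if (w_lit && !is.na(w_anchor)) {
    # unmapped association (e.g. has): bridge subject to the literal's
    # anchored column through the graph
    start <- var_position(state, sg, v, var_concepts)
    if (!is.null(start)) {
      res <- ground_via_path(state, sg, start, w_anchor)
      if (!is.null(res)) {
        st <- res$state
        if (start$kind == "concept" && !is.null(res$first_col)) {
          st <- state_bind(st, v, res$first_col)
        }
        st <- state_add_conjunct(st, cj_lit(res$end_col, w))
        options[[length(options) + 1L]] <- st
      }
    }
    if (is.na(target_concept)) target_concept <- concept_of_ref(sg, w_anchor)
  }

  # (3a) the predicate itself is a registered binary function (homolog)
  fn_names <- names(registry$functions)
  hit <- fn_names[str_to_lower(fn_names) == str_to_lower(a$predicate)]
  for (fnm in hit) {
    entry <- registry$functions[[fnm]]
    if (length(entry$inputs) != 2L || entry$mode == "live") next
    args <- list(
      if (a$lits[1L]) fn_arg_lit(v) else fn_arg_var(v),
      if (w_lit) fn_arg_lit(w) else fn_arg_var(w))
    options[[length(options) + 1L]] <-
      state_add_conjunct(state, cj_fn(fnm, args))
  }

  # (3b) a unary function producing the object's concept grounds
  # `a(V, literal)` as  Fn(V) = literal  (the cooperative variant)
  if (w_lit) {
    if (is.na(target_concept) && !is.na(w_anchor)) {
      target_concept <- concept_of_ref(sg, w_anchor)
    }
    tc_type <- NA_character_
    if (!is.na(target_concept)) {
      oc <- sg$ontology$concepts
      tc_type <- oc$type[oc$name == target_concept] %or% NA_character_
    }
    for (fnm in sort_c(fn_names)) {
      entry <- registry$functions[[fnm]]
      if (length(entry$inputs) != 1L || entry$mode == "live") next
      if (!is.na(target_concept) &&
          (entry$output == target_concept ||
           (!is.na(tc_type) && entry$output == tc_type))) {
        options[[length(options) + 1L]] <-
          state_add_conjunct(state, cj_fn(fnm, list(fn_arg_var(v)), value = w))
      }
    }
  }
  options
}

ground_atom <- function(state, sg, registry, a, var_concepts) {
  if (a$predicate == "@eq") return(list(state))   # handled in the final pass
  if (a$predicate == "@prop") {
    start <- var_position(state, sg, a$args[1L], var_concepts)
    if (is.null(start)) return(list())
    res <- ground_via_path(state, sg, start, a$anchors[2L])
    if (is.null(res)) return(list())
    st <- res$state
    if (start$kind == "concept" && !is.null(res$first_col)) {
      st <- state_bind(st, a$args[1L], res$first_col)
    }
    return(list(state_add_conjunct(st, cj_lit(res$end_col, a$args[2L]))))
  }
  if (a$predicate == "@path") {
    tc <- unname(var_concepts[a$args[2L]] %or% NA_character_)
    if (is.na(tc)) return(list())
    target_ref <- tryCatch(projection_for(paste0("concept:", tc), sg),
                           error = function(e) NA_character_)
    if (is.na(target_ref)) return(list())
    start <- var_position(state, sg, a$args[1L], var_concepts)
    if (is.null(start)) return(list())
    res <- ground_via_path(state, sg, start, target_ref)
    if (is.null(res)) return(list())
    st <- res$state
    if (start$kind == "concept" && !is.null(res$first_col)) {
      st <- state_bind(st, a$args[1L], res$first_col)
    }
    return(list(state_bind(st, a$args[2L], res$end_col)))
  }
  if (length(a$args) == 1L) return(ground_unary(state, sg, a, var_concepts))
  ground_binary(state, sg, registry, a, var_concepts)
}

# final pass: identity constraints, function-argument resolution, safety
finalize_state <- function(state, sg, registry, atoms, var_concepts) {
  for (a in atoms) {
    if (a$predicate != "@eq") next
    v <- a$args[1L]; val <- a$args[2L]; anchor <- a$anchors[2L]
    cols <- state$binds[[v]]
    if (is.null(cols)) {
      if (is.na(anchor)) return(NULL)
      parts <- split_ref(anchor)
      at <- state_add_table(state, parts$relation)
      state <- at$state
      state <- state_bind(state, v, state_col(at$alias, parts$attribute))
      cols <- state$binds[[v]]
    }
    state <- state_add_conjunct(state, cj_lit(cols[1L], val))
  }
  # resolve function arguments; unbound variables of an entity-mapped
  # concept get a domain table (Datalog safety)
  for (ci in seq_along(state$conjuncts)) {
    cj <- state$conjuncts[[ci]]
    if (!cj$type %in% c("fn_eq", "fn_notnull")) next
    for (ai in seq_along(cj$args)) {
      arg <- cj$args[[ai]]
      if (arg$kind != "var") next
      cols <- state$binds[[arg$value]]
      if (is.null(cols)) {
        cc <- unname(var_concepts[arg$value] %or% NA_character_)
        mu <- sg$cmap$mu
        murow <- mu[!is.na(cc) & mu$concept == cc, , drop = FALSE]
        if (nrow(murow) == 1L && murow$flavor == "entity") {
          rel <- murow$entity_relation
          at <- state_add_table(state, rel)
          state <- at$state
          col <- state_col(at$alias, sg$db$schemas[[rel]]$key[1L])
          state <- state_bind(state, arg$value, col)
          cols <- col
        } else {
          return(NULL)
        }
      }
      cj$args[[ai]] <- fn_arg_col(cols[1L])
    }
    state$conjuncts[[ci]] <- cj
  }
  if (is.null(state$binds[["X"]])) return(NULL)
  if (nrow(state$tables) == 0L) return(NULL)
  state
}

ground_derivation <- function(atoms, sg, registry, var_concepts) {
  # binary/structural atoms first (they create the join skeleton), then
  # unary domain atoms, identity constraints last
  rank <- map_int(atoms, function(a) {
    if (a$predicate == "@eq") 3L
    else if (length(a$args) == 1L && !startsWith(a$predicate, "@")) 2L
    else 1L
  })
  ordered <- atoms[order(rank)]
  states <- list(new_state())
  for (a in ordered) {
    nxt <- list()
    for (st in states) {
      nxt <- c(nxt, ground_atom(st, sg, registry, a, var_concepts))
    }
    states <- nxt
    if (length(states) == 0L) break
  }
  compact(map(states, finalize_state, sg = sg, registry = registry,
              atoms = ordered, var_concepts = var_concepts))
}
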