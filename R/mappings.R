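#' Map ontology concepts to database attributes
#'
#' Implements the concept-mapping function of the schema-graph
#' construction.  Every column whose inferred type is subsumed by a
#' concept's type node is a candidate for that concept; each column is
#' assigned to the most specific candidate concept (ties broken
#' lexicographically and logged), so concept-to-attribute mappings are
#' globally injective.  Within one relation, when several columns carry
#' the same concept, the mapping keeps the key column (else the first in
#' schema order); further *prime* columns of the same concept are
#' recorded as association partner columns (they realize
#' self-associations such as alias), and non-key ones are demoted and
#' later backward-mapped as unnamed properties of the key.
#'
#' A concept has an *entity* mapping when one of its columns is by itself
#' the primary key of its relation; all other non-empty mappings are
#' *property* mappings.
#'
#' @param o a [ontology()].
#' @param attr_types output of [infer_attribute_types()].
#' @param db a [database()].
#' @return a list with `attrs` (per-column tibble: `ref`, `relation`,
#'   `attribute`, `type`, `prime`, `concept`, `role`), `mu` (per-concept
#'   tibble: `concept`, `flavor`, `entity_relation`, `attrs` list-column)
#'   and `entity` (character vector of entity-mapped concepts).
#' @export
build_concept_mapping <- function(o, attr_types, db) {
  refs <- attribute_refs(db)
  at <- left_join(refs, attr_types[, c("ref", "type")], by = "ref")
  cdepth <- map_int(o$concepts$type, type_depth, th = o$types)

  assign_one <- function(ty) {
    if (nrow(o$concepts) == 0L) return(NA_character_)
    ok <- map_lgl(o$concepts$type, function(ct) type_subsumed(ty, ct, o$types))
    if (!any(ok)) return(NA_character_)
    cand <- o$concepts$name[ok]
    dep <- cdepth[ok]
    best <- sort_c(cand[dep == max(dep)])
    if (length(best) > 1L) {
      coop_log("concept assignment tie for type '", ty, "' between {",
               paste(best, collapse = ", "), "}; keeping '", best[1L], "'")
    }
    best[1L]
  }
  at$concept <- map_chr(at$type, assign_one)
  at$role <- ifelse(is.na(at$concept), NA_character_, "mapped")

  # within-relation consolidation: one representative column per
  # (concept, relation); prefer a sole-key column, then schema order
  for (rel in names(db$schemas)) {
    sc <- db$schemas[[rel]]
    idx <- which(at$relation == rel & !is.na(at$concept))
    for (cc in unique(at$concept[idx])) {
      grp <- idx[at$concept[idx] == cc]
      if (length(grp) <= 1L) next
      sole_key <- grp[at$attribute[grp] %in% sc$key &
                        map_lgl(at$attribute[grp], function(a) identical(sc$key, a))]
      kept <- if (length(sole_key) > 0L) sole_key[1L] else grp[1L]
      for (g in setdiff(grp, kept)) {
        at$role[g] <- if (at$prime[g]) "partner" else "demoted"
      }
    }
  }

  mapped <- filter(at, .data$role == "mapped")
  entity <- character()
  mu_rows <- map(sort_c(unique(mapped$concept)), function(cc) {
    rows <- filter(mapped, .data$concept == cc)
    ent_rel <- NA_character_
    for (i in seq_len(nrow(rows))) {
      sc <- db$schemas[[rows$relation[i]]]
      if (identical(sc$key, rows$attribute[i])) { ent_rel <- sc$name; break }
    }
    tibble(concept = cc,
           flavor = if (!is.na(ent_rel)) "entity" else "property",
           entity_relation = ent_rel,
           attrs = list(sort_c(rows$ref)))
  })
  mu <- bind_rows(mu_rows)
  if (nrow(mu) == 0L) {
    mu <- tibble(concept = character(), flavor = character(),
                 entity_relation = character(), attrs = list())
  }
  entity <- mu$concept[mu$flavor == "entity"]
  list(attrs = at, mu = mu, entity = entity)
}

#' Map ontology associations to attribute pairs
#'
#' An association `a(c, c')` receives a relationship mapping
#' `a -> <r.A, r.B>` in two cases.  Key-key (case i): both endpoint
#' concepts are entity-mapped elsewhere, and `r.A`, `r.B` are prime
#' attributes of the same relation `r` carrying `c` and `c'`
#' respectively (for self-associations `r.B` is the recorded partner
#' column).  Key-property (case ii): `c` is entity-mapped, `c'` is not,
#' and both columns lie in the same relation.  Associations with no
#' satisfying pair are recorded as unmapped rather than dropped.
#'
#' @param o a [ontology()].
#' @param cmap output of [build_concept_mapping()].
#' @param db a [database()].
#' @return a tibble: `association`, `source`, `target`, `relation`,
#'   `ref_a`, `ref_b`, `category` ("key-key", "key-property", or
#'   "unmapped" with `NA` refs).
#' @export
build_relationship_mappings <- function(o, cmap, db) {
  at <- cmap$attrs
  carriers <- function(cc, roles) filter(at, .data$concept %in% cc, .data$role %in% roles)
  out <- list()
  assoc <- o$associations
  for (i in seq_len(nrow(assoc))) {
    a <- assoc$name[i]; cs <- assoc$source[i]; ct <- assoc$target[i]
    pairs <- list()
    both_entity <- all(c(cs, ct) %in% cmap$entity)
    # case i: key-key inside a relationship relation
    if (both_entity) {
      for (rel in names(db$schemas)) {
        src_rows <- filter(carriers(cs, c("mapped", "partner")),
                           .data$relation == rel, .data$prime)
        tgt_rows <- filter(carriers(ct, c("mapped", "partner")),
                           .data$relation == rel, .data$prime)
        ent_rels <- cmap$mu$entity_relation[cmap$mu$concept %in% c(cs, ct)]
        if (rel %in% ent_rels) next   # keys must live in relations other than r
        for (ra in src_rows$ref) for (rb in tgt_rows$ref) {
          if (ra == rb) next
          if (cs == ct) {
            # self-association: orient representative -> partner
            role_a <- src_rows$role[src_rows$ref == ra]
            role_b <- tgt_rows$role[tgt_rows$ref == rb]
            if (!(role_a == "mapped" && role_b == "partner")) next
          }
          pairs[[length(pairs) + 1L]] <-
            tibble(association = a, source = cs, target = ct, relation = rel,
                   ref_a = ra, ref_b = rb, category = "key-key")
        }
      }
    }
    # case ii: entity key + property column of the same relation
    if (cs %in% cmap$entity && !ct %in% cmap$entity) {
      src_rows <- carriers(cs, "mapped")
      tgt_rows <- carriers(ct, "mapped")
      for (rel in intersect(src_rows$relation, tgt_rows$relation)) {
        ra <- src_rows$ref[src_rows$relation == rel]
        rb <- tgt_rows$ref[tgt_rows$relation == rel]
        for (x in ra) for (y in rb) {
          pairs[[length(pairs) + 1L]] <-
            tibble(association = a, source = cs, target = ct, relation = rel,
                   ref_a = x, ref_b = y, category = "key-property")
        }
      }
    }
    if (length(pairs) == 0L) {
      pairs[[1L]] <- tibble(association = a, source = cs, target = ct,
                            relation = NA_character_, ref_a = NA_character_,
                            ref_b = NA_character_, category = "unmapped")
    }
    out[[length(out) + 1L]] <- bind_rows(pairs)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(association = character(), source = character(),
                  target = character(), relation = character(),
                  ref_a = character(), ref_b = character(),
                  category = character())
  }
  distinct(arrange(res, .data$association, .data$ref_a, .data$ref_b))
}

#' Map value concepts to instance values
#'
#' Concepts with an empty attribute-level mapping (including undefined
#' predicates appearing in rules) are scanned against every column of the
#' instance; a match is a case-insensitive exact hit of the concept name
#' or of a lexicon synonym (rows whose lemma equals the concept name).
#' Each matching column is anchored: if an association of the same
#' relation has a key-key mapping `a -> <r.A, r.B>`, the value concept is
#' anchored as the relationship triple `<r.A, r.B, r.C>`; else it is
#' anchored to the relation's key as an entity property `<r.K, r.C>`.
#' Concepts matching no stored value are flagged
#' `function_resolvable_only`.
#'
#' @param o a [ontology()].
#' @param cmap output of [build_concept_mapping()].
#' @param rmap output of [build_relationship_mappings()].
#' @param db a [database()].
#' @param lex a [lexicon()].
#' @return a tibble: `concept`, `relation`, `attribute`, `ref`, `value`,
#'   `anchor_kind` ("relationship", "entity", or "none"), `anchor_a`,
#'   `anchor_b`.
#' @export
build_value_mappings <- function(o, cmap, rmap, db, lex) {
  mapped_concepts <- cmap$mu$concept %||% character()
  candidates <- sort_c(unique(c(
    setdiff(o$concepts$name, mapped_concepts),
    setdiff(o$undefined_predicates, c(mapped_concepts, o$associations$name)))))
  out <- list()
  for (cc in candidates) {
    synonyms <- unique(c(cc, lex$surface[!is.na(lex$lemma) & lex$lemma == cc]))
    hits <- list()
    for (rel in names(db$schemas)) {
      tb <- db$tables[[rel]]
      for (att in names(tb)) {
        vals <- unique(tb[[att]])
        hit <- vals[str_to_lower(vals) %in% str_to_lower(synonyms)]
        if (length(hit) == 0L) next
        key_pairs <- filter(rmap, .data$relation == rel, .data$category == "key-key")
        if (nrow(key_pairs) > 0L) {
          anchor_kind <- "relationship"
          anchor_a <- key_pairs$ref_a[1L]; anchor_b <- key_pairs$ref_b[1L]
        } else {
          anchor_kind <- "entity"
          anchor_a <- paste0(rel, ".", db$schemas[[rel]]$key[1L])
          anchor_b <- NA_character_
        }
        hits[[length(hits) + 1L]] <- tibble(
          concept = cc, relation = rel, attribute = att,
          ref = paste0(rel, ".", att), value = sort_c(hit)[1L],
          anchor_kind = anchor_kind, anchor_a = anchor_a, anchor_b = anchor_b)
      }
    }
    if (length(hits) == 0L) {
      out[[length(out) + 1L]] <- tibble(
        concept = cc, relation = NA_character_, attribute = NA_character_,
        ref = NA_character_, value = NA_character_,
        anchor_kind = "none", anchor_a = NA_character_, anchor_b = NA_character_)
    } else {
      out[[length(out) + 1L]] <- bind_rows(hits)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(concept = character(), relation = character(),
                  attribute = character(), ref = character(), value = character(),
                  anchor_kind = character(), anchor_a = character(),
                  anchor_b = character())
  }
  arrange(res, .data$concept, .data$ref)
}

#' Backward-map database structure into new concepts
#'
#' Columns the forward mapping left without an ontology home still need a
#' node in the schema graph, because users query in database vocabulary
#' too.  Every unmapped (or demoted) key column spawns a
#' database-derived concept; every unmapped non-key column spawns a
#' database-derived concept plus an unnamed property edge to its
#' relation's key column(s).  Derived concept names are the lower-cased
#' attribute name (suffixed with `_db` on a clash with an ontology
#' concept); two columns with the same derived name and type share one
#' concept.
#'
#' @param db a [database()].
#' @param cmap output of [build_concept_mapping()].
#' @param o a [ontology()].
#' @return a list with `concepts` (tibble `name`, `type`, `kind`,
#'   `attrs` list-column) and `property_edges` (tibble `from_ref`,
#'   `to_ref`).
#' @export
backward_map_database <- function(db, cmap, o) {
  at <- cmap$attrs
  uncovered <- filter(at, is.na(.data$concept) | .data$role == "demoted")
  edges <- list(); dc <- list()
  for (i in seq_len(nrow(uncovered))) {
    row <- uncovered[i, ]
    nm <- str_to_lower(gsub("[^A-Za-z0-9]", "", row$attribute))
    if (nm %in% o$concepts$name) nm <- paste0(nm, "_db")
    dc[[length(dc) + 1L]] <- tibble(name = nm, type = row$type, ref = row$ref)
    if (!row$prime) {
      sc <- db$schemas[[row$relation]]
      for (k in sc$key) {
        edges[[length(edges) + 1L]] <- tibble(
          from_ref = row$ref, to_ref = paste0(row$relation, ".", k))
      }
    }
  }
  concepts <- if (length(dc) > 0L) {
    bind_rows(dc) |>
      group_by(.data$name, .data$type) |>
      summarise(attrs = list(sort_c(.data$ref)), .groups = "drop") |>
      mutate(kind = "database-derived") |>
      arrange(.data$name)
  } else {
    tibble(name = character(), type = character(), attrs = list(),
           kind = character())
  }
  property_edges <- if (length(edges) > 0L) {
    arrange(distinct(bind_rows(edges)), .data$from_ref, .data$to_ref)
  } else {
    tibble(from_ref = character(), to_ref = character())
  }
  list(concepts = concepts, property_edges = property_edges)
}
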