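#' Bind query terms to schema-graph nodes
#'
#' Applies the part-of-speech correspondence: common nouns bind to
#' concepts (or concept properties), proper nouns and quoted strings bind
#' to stored instance values (value literals carrying a selection
#' predicate), transitive verbs bind to association names, and modifier
#' runs are first tried as one multiword value literal ("growth control")
#' before token-by-token matching — a value-literal reading wins over a
#' concept reading because it is more selective.  Stopwords, quantifiers
#' and unmatched tokens are dropped with a logged note.  Matching is
#' deterministic for a fixed lexicon and graph, and works at the lemma
#' level, so plural/case variants bind identically.
#'
#' A token may match several columns (e.g. an identifier stored in three
#' relations); all candidates are kept, and the graph connector picks the
#' candidate set minimizing path length.
#'
#' @param parsed a [parse_query()] result.
#' @param sg a [build_schema_graph()] result.
#' @return a tibble of class `coop_term_matches` with columns `role_id`,
#'   `part` (head/modifier/verb), `surface`, `lemma`, `node`,
#'   `match_kind` (exact-concept, synonym, type-subsumption,
#'   value-literal, association), `score`, `literal` (stored value for
#'   value literals), `candidate_group`.  Dropped tokens are recorded in
#'   `attr(, "dropped")`.
#' @export
match_terms <- function(parsed, sg) {
  lex <- sg$lexicon
  concept_ids <- sg$nodes$id[sg$nodes$kind == "concept"]
  concept_names <- sub("^concept:", "", concept_ids)
  concept_types <- c(
    stats::setNames(sg$ontology$concepts$type, sg$ontology$concepts$name),
    stats::setNames(sg$backward$concepts$type, sg$backward$concepts$name))

  out <- list(); dropped <- list(); grp <- 0L
  note_drop <- function(surface, reason) {
    dropped[[length(dropped) + 1L]] <<- tibble(surface = surface, reason = reason)
    coop_log("dropped query token '", surface, "': ", reason)
  }

  concept_match <- function(lemma) {
    if (lemma %in% concept_names) {
      return(tibble(node = paste0("concept:", lemma),
                    match_kind = "exact-concept", score = 1))
    }
    # synonym: lexicon maps the surface to a lemma naming a concept
    syn <- lex$lemma[lex$surface == lemma & !is.na(lex$lemma)]
    syn <- syn[syn %in% concept_names]
    if (length(syn) > 0L) {
      return(tibble(node = paste0("concept:", syn[1L]),
                    match_kind = "synonym", score = 0.85))
    }
    # type subsumption: the lemma names a type carried by some concept
    if (lemma %in% sg$ontology$types$nodes) {
      carriers <- sort_c(names(concept_types)[
        !is.na(concept_types) & concept_types == lemma &
          names(concept_types) %in% concept_names])
      if (length(carriers) > 0L) {
        return(tibble(node = paste0("concept:", carriers[1L]),
                      match_kind = "type-subsumption", score = 0.8))
      }
    }
    NULL
  }

  value_match <- function(surface, lemma) {
    hit <- which(lex$surface %in% str_to_lower(c(surface, lemma)) &
                   !is.na(lex$canonical))
    needles <- unique(c(
      if (length(hit) > 0L) lex$canonical[hit[1L]], surface, lemma))
    for (needle in needles) {
      hits <- sg_value_hits(sg, needle)
      if (nrow(hits) > 0L) {
        return(mutate(
          tibble(node = paste0("attr:", hits$ref), match_kind = "value-literal",
                 score = 0.9),
          literal = hits$stored))
      }
    }
    # cooperative fallback: the lexicon knows the term's canonical value
    # and type, so anchor it to same-typed columns even when no stored row
    # carries the value (the answer may still be derivable by rules)
    if (length(hit) > 0L && !is.na(lex$type[hit[1L]])) {
      refs <- sg$attr_types$ref[sg$attr_types$type == lex$type[hit[1L]]]
      if (length(refs) > 0L) {
        return(tibble(node = paste0("attr:", sort_c(refs)),
                      match_kind = "value-literal", score = 0.85,
                      literal = lex$canonical[hit[1L]]))
      }
    }
    NULL
  }

  add_rows <- function(rows, role_id, part, surface, lemma) {
    grp <<- grp + 1L
    rows$role_id <- role_id; rows$part <- part
    rows$surface <- surface; rows$lemma <- lemma
    rows$candidate_group <- grp
    if (!"literal" %in% names(rows)) rows$literal <- NA_character_
    out[[length(out) + 1L]] <<- rows
  }

  for (i in seq_len(nrow(parsed$roles))) {
    role <- parsed$roles[i, ]
    rid <- role$role_id
    mods <- role$modifiers[[1L]]

    # head noun: concept first, then value literal (e.g. "... in dogs")
    cm <- concept_match(role$head_lemma)
    vm <- NULL
    if (is.null(cm)) vm <- value_match(role$head_surface, role$head_lemma)
    if (!is.null(cm)) {
      add_rows(cm, rid, "head", role$head_surface, role$head_lemma)
    } else if (!is.null(vm)) {
      add_rows(vm, rid, "head", role$head_surface, role$head_lemma)
    } else {
      note_drop(role$head_surface, "no concept or value match")
    }

    # modifiers: multiword literal first, then token-by-token
    consumed <- rep(FALSE, nrow(mods))
    word_mods <- which(mods$pos %in% c("noun", "adj"))
    if (length(word_mods) > 1L) {
      phrase <- paste(mods$lemma[word_mods], collapse = " ")
      pm <- value_match(phrase, phrase)
      if (!is.null(pm)) {
        add_rows(pm, rid, "modifier", phrase, phrase)
        consumed[word_mods] <- TRUE
      }
    }
    for (j in seq_len(nrow(mods))) {
      if (consumed[j]) next
      s <- mods$surface[j]; l <- mods$lemma[j]
      vm <- value_match(s, l)
      if (!is.null(vm)) { add_rows(vm, rid, "modifier", s, l); next }
      cm <- if (mods$pos[j] != "propn") concept_match(l) else NULL
      if (!is.null(cm)) { add_rows(cm, rid, "modifier", s, l); next }
      note_drop(s, "no concept or value match")
    }
  }

  # transitive verbs bind to association names
  assoc_names <- unique(sg$rmap$association[sg$rmap$category != "unmapped"])
  for (v in parsed$verbs) {
    if (v %in% assoc_names) {
      add_rows(tibble(node = paste0("assoc:", v), match_kind = "association",
                      score = 0.9),
               NA_integer_, "verb", v, v)
    } else if (!v %in% IMPERATIVE_VERBS) {
      note_drop(v, "verb matches no mapped association")
    }
  }

  matches <- bind_rows(out)
  if (nrow(matches) == 0L) {
    stop_coop(paste0("no query term could be grounded in the schema graph: '",
                     parsed$text, "'"), "no_match_error")
  }
  matches <- matches[, c("role_id", "part", "surface", "lemma", "node",
                         "match_kind", "score", "literal", "candidate_group")]
  attr(matches, "dropped") <- if (length(dropped)) bind_rows(dropped) else
    tibble(surface = character(), reason = character())
  attr(matches, "parsed") <- parsed
  class(matches) <- c("coop_term_matches", class(matches))
  matches
}

#' @export
print.coop_term_matches <- function(x, ...) {
  cat("<coop_term_matches> ", length(unique(x$candidate_group)),
      " bound terms\n", sep = "")
  NextMethod()
}
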