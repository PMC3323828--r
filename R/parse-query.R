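DETERMINERS <- c("a", "an", "the", "all", "every", "each", "any", "some")
PREPOSITIONS <- c("in", "of", "to", "for", "from", "with", "on", "by", "that")
AUXILIARIES <- c("does", "is", "do", "was", "were", "can", "could")
WH_WORDS <- c("what", "which", "who", "why", "how", "where", "when")
IMPERATIVE_VERBS <- c("list", "print", "return", "show", "find", "give",
                      "display")

#' Parse a short English query into semantic roles
#'
#' A deterministic pattern-based parser backend: it lemmatizes and
#' POS-tags tokens (lexicon first, then shape heuristics), classifies the
#' query as imperative ("List/Print/Return ..."), interrogative
#' ("Does/Is/What/Which ...") or declarative, and extracts semantic
#' roles: contiguous noun groups become a role with the last common noun
#' as head and the remaining nouns/adjectives/proper nouns as modifiers;
#' a role introduced by a preposition records it.  Verbs relate
#' consecutive roles.  Real dependency parsers can replace this backend
#' behind the same contract (`parser` argument of [ask()]); the fallback
#' covers the imperative/existential query families the pipeline targets.
#'
#' @param text the query string.
#' @param lex a [lexicon()] supplying lemmas and parts of speech.
#' @return an object of class `coop_parsed_query`: `tokens` (tibble
#'   surface/lemma/pos), `roles` (tibble role_id/head_surface/head_lemma/
#'   prep with a `modifiers` list-column), `verbs`, `dependencies`,
#'   `query_type`.
#' @export
parse_query <- function(text, lex) {
  raw <- str_trim(text %||% "")
  raw <- gsub("[?.!]+\\s*$", "", raw)
  if (!nzchar(raw)) {
    stop_coop("cannot parse an empty query", "parse_error",
              tokens = character())
  }
  # quoted phrases survive as single tokens
  pieces <- regmatches(raw, gregexpr("\"[^\"]*\"|'[^']*'|[^\\s,]+", raw, perl = TRUE))[[1]]
  surfaces <- gsub("^[\"']|[\"']$", "", pieces)
  quoted <- grepl("^[\"']", pieces)

  tag_one <- function(surface, is_quoted, first) {
    low <- str_to_lower(surface)
    hit <- which(lex$surface == low)
    if (length(hit) > 0L && !is.na(lex$pos[hit[1L]])) {
      return(list(lemma = lex$lemma[hit[1L]], pos = lex$pos[hit[1L]]))
    }
    if (is_quoted) return(list(lemma = surface, pos = "propn"))
    if (low %in% DETERMINERS) return(list(lemma = low, pos = "det"))
    if (low %in% AUXILIARIES) return(list(lemma = low, pos = "aux"))
    if (low %in% WH_WORDS) return(list(lemma = low, pos = "wh"))
    if (low %in% PREPOSITIONS) return(list(lemma = low, pos = "prep"))
    if (first && low %in% IMPERATIVE_VERBS) return(list(lemma = low, pos = "verb"))
    if (grepl("^[0-9]+$", surface) ||
        (grepl("[0-9]", surface) && grepl("^[A-Za-z0-9_-]+$", surface)) ||
        grepl("^[A-Z][A-Z0-9-]+$", surface)) {
      return(list(lemma = surface, pos = "propn"))
    }
    if (length(hit) > 0L) {
      return(list(lemma = lex$lemma[hit[1L]], pos = "noun"))
    }
    lemma <- if (grepl("ies$", low)) sub("ies$", "y", low)
             else if (grepl("[^s]s$", low)) sub("s$", "", low) else low
    list(lemma = lemma, pos = "noun")
  }
  tags <- map2(surfaces, seq_along(surfaces),
               function(s, i) tag_one(s, quoted[i], i == 1L))
  tokens <- tibble(surface = surfaces,
                   lemma = map_chr(tags, "lemma"),
                   pos = map_chr(tags, "pos"))

  first_low <- str_to_lower(surfaces[1L])
  query_type <-
    if (tokens$pos[1L] == "verb" && first_low %in% IMPERATIVE_VERBS) "imperative"
    else if (first_low %in% c("does", "is", "are", "do")) "interrogative-existential"
    else if (first_low %in% WH_WORDS) "interrogative"
    else "declarative"

  # group contiguous noun/propn/adj runs into semantic roles
  roles <- list(); deps <- list()
  i <- 1L; pending_prep <- NA_character_; last_verb <- NA_character_
  last_role <- NA_integer_
  content <- c("noun", "propn", "adj")
  while (i <= nrow(tokens)) {
    pos <- tokens$pos[i]
    if (pos %in% content) {
      j <- i
      while (j < nrow(tokens) && tokens$pos[j + 1L] %in% content) j <- j + 1L
      grp <- tokens[i:j, ]
      noun_idx <- which(grp$pos == "noun")
      head_idx <- if (length(noun_idx) > 0L) max(noun_idx) else nrow(grp)
      rid <- length(roles) + 1L
      roles[[rid]] <- tibble(
        role_id = rid,
        head_surface = grp$surface[head_idx],
        head_lemma = grp$lemma[head_idx],
        head_pos = grp$pos[head_idx],
        prep = pending_prep,
        modifiers = list(grp[-head_idx, , drop = FALSE]))
      if (!is.na(last_verb)) {
        deps[[length(deps) + 1L]] <- tibble(
          governor = last_verb, relation = "obj",
          dependent = grp$lemma[head_idx])
        last_verb <- NA_character_
      }
      if (!is.na(pending_prep) && !is.na(last_role)) {
        deps[[length(deps) + 1L]] <- tibble(
          governor = roles[[last_role]]$head_lemma,
          relation = paste0("prep_", pending_prep),
          dependent = grp$lemma[head_idx])
      }
      pending_prep <- NA_character_
      last_role <- rid
      i <- j + 1L
    } else {
      if (pos == "prep") pending_prep <- tokens$lemma[i]
      if (pos == "verb") {
        last_verb <- tokens$lemma[i]
        if (!is.na(last_role)) {
          deps[[length(deps) + 1L]] <- tibble(
            governor = tokens$lemma[i], relation = "subj",
            dependent = roles[[last_role]]$head_lemma)
        }
      }
      i <- i + 1L
    }
  }
  if (length(roles) == 0L) {
    stop_coop(paste0("no semantic roles recognized in: '", raw, "'"),
              "parse_error", tokens = tokens$surface)
  }
  structure(
    list(text = raw, tokens = tokens, roles = bind_rows(roles),
         verbs = unique(tokens$lemma[tokens$pos == "verb"]),
         dependencies = if (length(deps)) bind_rows(deps) else
           tibble(governor = character(), relation = character(),
                  dependent = character()),
         query_type = query_type),
    class = "coop_parsed_query")
}

#' @export
print.coop_parsed_query <- function(x, ...) {
  cat("<coop_parsed_query> \"", x$text, "\" (", x$query_type, ")\n", sep = "")
  for (i in seq_len(nrow(x$roles))) {
    mods <- x$roles$modifiers[[i]]
    cat("  role ", i, ": head '", x$roles$head_lemma[i], "'",
        if (nrow(mods) > 0L) paste0(" modifiers {",
                                    paste(mods$surface, collapse = ", "), "}"),
        if (!is.na(x$roles$prep[i])) paste0(" [", x$roles$prep[i], "]"),
        "\n", sep = "")
  }
  if (length(x$verbs) > 0L) cat("  verbs:", paste(x$verbs, collapse = ", "), "\n")
  invisible(x)
}
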