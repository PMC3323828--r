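#' Build a type hierarchy
#'
#' A type hierarchy is a rooted tree of type identifiers used to classify
#' column values and ontology concepts.  Subsumption runs child to parent:
#' every node reaches the single root, and the least upper bound of any
#' non-empty node set is defined.
#'
#' @param edges a data frame (or tibble) with columns `child` and `parent`,
#'   or a list of length-2 character vectors `c(child, parent)`.
#' @param root the root type identifier.  Defaults to the unique parent
#'   that is never a child.
#' @return an object of class `coop_type_hierarchy` with fields `nodes`,
#'   `edges` (tibble child/parent) and `root`.
#' @examples
#' th <- type_hierarchy(list(c("gene", "entity"), c("protein", "entity")))
#' type_lub(c("gene", "protein"), th)
#' @export
type_hierarchy <- function(edges, root = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- tibble(
      child = map_chr(edges, 1),
      parent = map_chr(edges, 2)
    )
  }
  edges <- as_tibble(edges)[, c("child", "parent")]
  nodes <- sort_c(unique(c(edges$child, edges$parent)))
  parent_of <- stats::setNames(edges$parent, edges$child)
  if (anyDuplicated(edges$child) > 0L) {
    stop_coop("type hierarchy is not a tree: a node has two parents", "type_error")
  }
  roots <- setdiff(nodes, edges$child)
  if (is.null(root)) {
    if (length(roots) != 1L) {
      stop_coop(
        paste0("type hierarchy must have a single root; found: ",
               paste(roots, collapse = ", ")),
        "type_error")
    }
    root <- roots
  }
  # acyclicity: walking parents from any node must terminate at the root
  for (nd in nodes) {
    seen <- character()
    cur <- nd
    while (cur != root) {
      if (cur %in% seen) stop_coop("type hierarchy contains a cycle", "type_error")
      seen <- c(seen, cur)
      nxt <- unname(parent_of[cur])
      if (is.na(nxt)) stop_coop(
        paste0("type node '", cur, "' does not reach the root"), "type_error")
      cur <- nxt
    }
  }
  structure(
    list(nodes = nodes, edges = edges, root = root, parent_of = parent_of),
    class = "coop_type_hierarchy")
}

#' @export
print.coop_type_hierarchy <- function(x, ...) {
  cat("<coop_type_hierarchy> ", length(x$nodes), " types, root '", x$root, "'\n",
      sep = "")
  invisible(x)
}

# ancestor chain from node up to (and including) the root
type_ancestors <- function(type, th) {
  if (!type %in% th$nodes) {
    stop_coop(paste0("unknown type '", type, "'"), "type_error")
  }
  chain <- type
  cur <- type
  while (cur != th$root) {
    cur <- unname(th$parent_of[cur])
    chain <- c(chain, cur)
  }
  chain
}

type_depth <- function(type, th) length(type_ancestors(type, th)) - 1L

# is `a` subsumed by (a descendant-or-equal of) `b`?
type_subsumed <- function(a, b, th) b %in% type_ancestors(a, th)

#' Least upper bound of a set of types
#'
#' Returns the deepest type that is an ancestor-or-equal of every input
#' type.  With a tree-shaped hierarchy the least upper bound is unique;
#' should several minimal common ancestors tie in depth, the
#' lexicographically smallest is returned and the tie is logged (enable
#' `options(coopquery.verbose = TRUE)` to see tie notes).
#'
#' @param types character vector of type identifiers (non-empty).
#' @param th a [type_hierarchy()].
#' @return a single type identifier.
#' @export
type_lub <- function(types, th) {
  types <- unique(types)
  if (length(types) == 0L) stop_coop("type_lub() needs at least one type", "type_error")
  chains <- map(types, type_ancestors, th = th)
  common <- Reduce(intersect, chains)
  depths <- map_int(common, type_depth, th = th)
  best <- common[depths == max(depths)]
  if (length(best) > 1L) {
    best <- sort_c(best)
    coop_log("type_lub tie between {", paste(best, collapse = ", "),
             "}; keeping '", best[1L], "'")
  }
  best[1L]
}

coop_log <- function(...) {
  if (isTRUE(getOption("coopquery.verbose", FALSE))) {
    inform(paste0(...))
  }
  invisible(NULL)
}

# ---- rule language ---------------------------------------------------------

# An atom is predicate(args...); arguments starting with an upper-case
# letter are variables, everything else (including quoted strings and
# numbers) is a constant.
atom <- function(predicate, args) {
  structure(list(predicate = predicate, arity = length(args),
                 args = as.character(args)), class = "coop_atom")
}

is_rule_var <- function(x) grepl("^[A-Z]", x) & !grepl("^'", x)

atom_text <- function(a) paste0(a$predicate, "(", paste(a$args, collapse = ", "), ")")

parse_atom <- function(text) {
  m <- regmatches(text, regexec("^\\s*([A-Za-z_][A-Za-z0-9_ -]*?)\\s*\\(([^()]*)\\)\\s*$", text))[[1]]
  if (length(m) == 0L) {
    stop_coop(paste0("cannot parse atom: '", text, "'"), "rule_parse_error")
  }
  args <- str_trim(strsplit(m[3], ",", fixed = TRUE)[[1]])
  args <- args[nzchar(args)]
  if (!length(args) %in% c(1L, 2L)) {
    stop_coop(paste0("atom '", text, "' must be unary or binary"), "rule_parse_error")
  }
  atom(str_trim(m[2]), args)
}

#' Parse an inference rule written as `head <- body1, body2`
#'
#' Rules are Horn clauses over unary predicates (concepts, written
#' `concept(X)`) and binary predicates (associations, written
#' `assoc(X, Y)`).  Every head variable must occur in the body (range
#' restriction).  `<-` and the arrow `←` are both accepted.
#'
#' @param text a single rule string.
#' @param rule_id identifier for the rule; defaults to `r<n>` assigned by
#'   the caller.
#' @return a list with fields `rule_id`, `head` (atom), `body` (list of
#'   atoms) and `text`.
#' @export
parse_rule <- function(text, rule_id = "r1") {
  raw <- gsub("←", "<-", text, fixed = TRUE)
  parts <- strsplit(raw, "<-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop_coop(paste0("rule must contain one '<-': '", text, "'"), "rule_parse_error")
  }
  head_atom <- parse_atom(parts[1])
  # split the body on commas that sit outside parentheses
  body_txt <- parts[2]
  depth <- 0L
  cut <- integer()
  chars <- strsplit(body_txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, nchar(body_txt))
  body <- map2(starts, ends, function(s, e) parse_atom(substr(body_txt, s, e)))
  if (length(body) == 0L) {
    stop_coop(paste0("rule body is empty: '", text, "'"), "rule_parse_error")
  }
  head_vars <- head_atom$args[is_rule_var(head_atom$args)]
  body_vars <- unique(unlist(map(body, function(a) a$args[is_rule_var(a$args)])))
  missing_vars <- setdiff(head_vars, body_vars)
  if (length(missing_vars) > 0L) {
    stop_coop(
      paste0("rule '", text, "' is not range-restricted: head variable(s) ",
             paste(missing_vars, collapse = ", "), " absent from body"),
      "rule_validation_error")
  }
  list(rule_id = rule_id, head = head_atom, body = body, text = str_trim(text))
}

render_rule <- function(rule) {
  paste0(atom_text(rule$head), " <- ",
         paste(map_chr(rule$body, atom_text), collapse = ", "))
}

# ---- ontology --------------------------------------------------------------

#' Construct an ontology
#'
#' An ontology bundles a set of named concepts, binary associations
#' between concepts, Horn-style inference rules, and a type hierarchy.
#' Predicates appearing in rules that are neither declared concepts nor
#' associations are retained and flagged as *undefined*: they are
#' expected to be computed or represented in the database (as instance
#' values or external functions) and are resolved during schema-graph
#' construction.
#'
#' @param concepts character vector of concept names, or a data frame
#'   with columns `name` and optional `type` (type-hierarchy node; defaults
#'   to the concept name when that node exists, else the root).
#' @param associations data frame with columns `name`, `source`, `target`,
#'   or a list of named lists.
#' @param rules character vector of rule strings (see [parse_rule()]).
#' @param types a [type_hierarchy()], or `NULL` for a trivial one-node tree.
#' @return an object of class `coop_ontology`.
#' @export
ontology <- function(concepts = character(), associations = NULL,
                     rules = character(), types = NULL) {
  if (is.null(types)) {
    types <- type_hierarchy(tibble(child = "anything", parent = "entity"))
  }
  if (is.character(concepts)) {
    concepts <- tibble(name = concepts, type = NA_character_)
  }
  concepts <- as_tibble(concepts)
  if (!"type" %in% names(concepts)) concepts$type <- NA_character_
  concepts$type <- ifelse(
    is.na(concepts$type),
    ifelse(concepts$name %in% types$nodes, concepts$name, types$root),
    concepts$type)
  if (anyDuplicated(concepts$name) > 0L) {
    stop_coop("concept names must be unique", "ontology_validation_error")
  }
  bad_type <- setdiff(concepts$type, types$nodes)
  if (length(bad_type) > 0L) {
    stop_coop(paste0("concept type node(s) not in hierarchy: ",
                     paste(bad_type, collapse = ", ")),
              "ontology_validation_error")
  }
  concepts$kind <- "class"

  if (is.null(associations) ||
      (is.list(associations) && !is.data.frame(associations) &&
         length(associations) == 0L)) {
    associations <- tibble(name = character(), source = character(),
                           target = character())
  } else if (is.list(associations) && !is.data.frame(associations)) {
    associations <- bind_rows(map(associations, as_tibble))
  }
  associations <- as_tibble(associations)[, c("name", "source", "target")]
  bad_end <- setdiff(c(associations$source, associations$target), concepts$name)
  if (length(bad_end) > 0L) {
    stop_coop(paste0("association endpoint(s) not declared as concepts: ",
                     paste(sort_c(unique(bad_end)), collapse = ", ")),
              "ontology_validation_error")
  }

  parsed <- map2(rules, seq_along(rules),
                 function(txt, i) parse_rule(txt, rule_id = paste0("r", i)))
  # arity consistency across rules (unary concept and binary association
  # namespaces are separate, so one name may legally appear in both the
  # concept and association declarations)
  rule_arity <- integer()
  undefined <- character()
  for (rl in parsed) {
    for (a in c(list(rl$head), rl$body)) {
      known <- rule_arity[a$predicate]
      if (!is.na(known) && known != a$arity) {
        stop_coop(paste0("predicate '", a$predicate,
                         "' used with inconsistent arity in rule '", rl$text, "'"),
                  "ontology_validation_error")
      }
      rule_arity[a$predicate] <- a$arity
      defined <- if (a$arity == 1L) a$predicate %in% concepts$name else
        a$predicate %in% associations$name
      if (!defined) undefined <- c(undefined, a$predicate)
    }
  }
  undefined <- sort_c(unique(undefined))
  if (length(undefined) > 0L) {
    coop_log("undefined-but-legal predicates in rules: ",
             paste(undefined, collapse = ", "))
  }
  structure(
    list(concepts = concepts, associations = associations, rules = parsed,
         types = types, undefined_predicates = undefined),
    class = "coop_ontology")
}

#' @export
print.coop_ontology <- function(x, ...) {
  cat("<coop_ontology> ", nrow(x$concepts), " concepts, ",
      nrow(x$associations), " associations, ", length(x$rules), " rules, ",
      length(x$types$nodes), " types\n", sep = "")
  if (length(x$undefined_predicates) > 0L) {
    cat("  undefined (database/function-resolved) predicates: ",
        paste(x$undefined_predicates, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read an ontology from a YAML file
#'
#' The file dialect has four top-level keys: `concepts` (list of names or
#' of `{name, type}` maps), `associations` (list of `{name, source,
#' target}` maps), `types` (`{root, edges}` where edges are `[child,
#' parent]` pairs) and `rules` (list of `head <- body1, body2` strings).
#'
#' @param path path to the YAML file.
#' @return a `coop_ontology`.
#' @seealso [write_ontology()]
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) {
    stop_coop(paste0("ontology file not found: ", path), "io_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_coop(
      paste0("malformed ontology file ", path, ": ", conditionMessage(e)),
      "parse_error"))
  th <- NULL
  if (!is.null(doc$types)) {
    th <- type_hierarchy(doc$types$edges, root = doc$types$root)
  }
  concepts <- doc$concepts %||% list()
  if (length(concepts) == 0L) {
    concepts <- tibble(name = character(), type = character())
  } else if (is.list(concepts)) {
    concepts <- bind_rows(map(concepts, function(cc) {
      if (is.character(cc) && length(cc) == 1L) {
        tibble(name = cc, type = NA_character_)
      } else {
        tibble(name = cc$name, type = cc$type %||% NA_character_)
      }
    }))
  } else if (is.character(concepts)) {
    concepts <- tibble(name = concepts, type = NA_character_)
  }
  ontology(
    concepts = concepts,
    associations = doc$associations,
    rules = as.character(doc$rules %||% character()),
    types = th)
}

#' Write an ontology to a YAML file
#'
#' Serializes with [read_ontology()]'s dialect; reading the result back
#' reproduces the ontology (round-trip identity).
#'
#' @param x a `coop_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(x, path) {
  doc <- list(
    concepts = pmap(list(x$concepts$name, x$concepts$type),
                    function(n, t) list(name = n, type = t)),
    associations = pmap(
      list(x$associations$name, x$associations$source, x$associations$target),
      function(n, s, t) list(name = n, source = s, target = t)),
    types = list(
      root = x$types$root,
      edges = pmap(list(x$types$edges$child, x$types$edges$parent),
                   function(ch, pa) list(ch, pa))),
    rules = map_chr(x$rules, "text"))
  yaml::write_yaml(doc, path)
  invisible(path)
}

# rules whose head predicate equals `pred`
rules_for <- function(o, pred) keep(o$rules, function(r) r$head$predicate == pred)
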