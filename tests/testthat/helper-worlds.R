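# Shared fixtures, built once per test run.

.coop_cache <- new.env(parent = emptyenv())

delta_world <- function() {
  if (is.null(.coop_cache$world)) .coop_cache$world <- build_delta()
  .coop_cache$world
}

delta_graph <- function() {
  if (is.null(.coop_cache$sg)) {
    w <- delta_world()
    .coop_cache$sg <- build_schema_graph(w$db, w$ontology, w$registry, w$lexicon)
  }
  .coop_cache$sg
}

# the example world minus the Gene row that answers the dogs query directly
delta_without_dog_gene <- function() {
  w <- delta_world()
  w$db$tables$Gene <- w$db$tables$Gene[w$db$tables$Gene$GeneID != "LOC608882", ]
  w
}

# a deliberately two-island world: no type is shared between the two
# relations, so their concepts live in disconnected graph components
island_world <- function() {
  th <- type_hierarchy(list(c("t1", "entity"), c("t2", "entity")))
  o <- ontology(
    concepts = tibble::tibble(name = c("c1", "c2"), type = c("t1", "t2")),
    associations = NULL, rules = character(), types = th)
  db <- database(
    schemas = list(relation_schema("R1", c("A", "B"), key = "A"),
                   relation_schema("R2", c("C", "D"), key = "C")),
    tables = list(
      R1 = tibble::tibble(A = paste0("t1::k", 1:3), B = paste0("t1::v", 1:3)),
      R2 = tibble::tibble(C = paste0("t2::k", 1:3), D = paste0("t2::v", 1:3))))
  lex <- lexicon(tibble::tibble(
    surface = c("c1", "c1s", "c2", "c2s"),
    lemma = c("c1", "c1", "c2", "c2"),
    pos = "noun"))
  structure(list(db = db, ontology = o, lexicon = lex,
                 registry = function_registry()),
            class = "coop_world")
}

# independent breadth-first search used as the shortest-path oracle on
# unit-weight graphs
bfs_distance <- function(edge_df, from, to) {
  nodes <- unique(c(edge_df$from, edge_df$to, from, to))
  adj <- lapply(stats::setNames(nodes, nodes), function(n) {
    c(edge_df$to[edge_df$from == n], edge_df$from[edge_df$to == n])
  })
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  unname(dist[to])
}

# independent exhaustive rule-unfolding enumerator (recursive, no
# frontier bookkeeping), reported as canonical strings
oracle_unfold <- function(atoms, rules, depth) {
  canon <- coopquery:::canon_atoms
  out <- canon(atoms)
  if (depth == 0L) return(out)
  for (i in seq_along(atoms)) {
    a <- atoms[[i]]
    if (startsWith(a$predicate, "@")) next
    for (rl in rules) {
      if (rl$head$predicate != a$predicate || rl$head$arity != length(a$args)) next
      bind <- stats::setNames(seq_along(rl$head$args), rl$head$args)
      stamp <- sample.int(1e9, 1)   # one consistent renaming per application
      body <- lapply(rl$body, function(b) {
        args <- character(length(b$args)); lits <- logical(length(b$args))
        anchors <- rep(NA_character_, length(b$args))
        for (k in seq_along(b$args)) {
          arg <- b$args[k]
          if (coopquery:::is_rule_var(arg) && arg %in% names(bind)) {
            slot <- bind[[arg]]
            args[k] <- a$args[slot]; lits[k] <- a$lits[slot]
            anchors[k] <- a$anchors[slot]
          } else if (coopquery:::is_rule_var(arg)) {
            args[k] <- paste0("O", arg, "_", stamp)
          } else {
            args[k] <- arg; lits[k] <- TRUE
          }
        }
        coopquery:::catom(b$predicate, args, lits, anchors)
      })
      rewritten <- c(atoms[seq_len(i - 1L)], body, atoms[-seq_len(i)])
      out <- c(out, oracle_unfold(rewritten, rules, depth - 1L))
    }
  }
  unique(out)
}

expect_setequal_chr <- function(actual, expected) {
  expect_setequal(sort(actual), sort(expected))
}
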