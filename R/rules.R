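# Conjunctive-atom form of a query.  An atom has a predicate, character
# args, a logical mask `lits` marking constant (literal) arguments, and
# `anchors`: for literals, the column that originally anchored the value;
# for variables, NA.  Predicates starting with "@" are structural
# (equality, property, path link) and are never rewritten by rules.
catom <- function(predicate, args, lits = rep(FALSE, length(args)),
                  anchors = rep(NA_character_, length(args))) {
  list(predicate = predicate, args = as.character(args), lits = lits,
       anchors = anchors)
}

catom_text <- function(a) {
  paste0(a$predicate, "(",
         paste(ifelse(a$lits, paste0("'", a$args, "'"), a$args), collapse = ", "),
         ")")
}

atoms_text <- function(atoms) paste(map_chr(atoms, catom_text), collapse = ", ")

# canonical form modulo variable renaming, for duplicate elimination
canon_atoms <- function(atoms) {
  keys <- map_chr(atoms, function(a) {
    paste0(a$predicate, "(",
           paste(ifelse(a$lits, paste0("'", a$args, "'"), "?"), collapse = ","), ")")
  })
  ord <- order(keys, method = "radix")
  mapping <- character(); n <- 0L
  rendered <- map_chr(ord, function(i) {
    a <- atoms[[i]]
    shown <- map2(a$args, a$lits, function(arg, lit) {
      if (lit) return(paste0("'", arg, "'"))
      if (is.na(mapping[arg] %or% NA_character_)) {
        n <<- n + 1L
        mapping[arg] <<- paste0("v", n)
      }
      mapping[[arg]]
    })
    paste0(a$predicate, "(", paste(unlist(shown), collapse = ","), ")")
  })
  paste(rendered, collapse = ";")
}

# translate a logical query graph into conjunctive-atom form: the answer
# variable X carries the head concept; each selection becomes either an
# identity constraint (literal on the head concept's own column), an
# association atom a(X, 'literal'), or a structural property atom; verb
# matches become association atoms between role variables
lqg_to_atoms <- function(lqg, sg) {
  atoms <- list()
  head_cc <- lqg$head_concept
  var_concepts <- c(X = head_cc)
  if (startsWith(lqg$head_node, "concept:")) {
    atoms[[length(atoms) + 1L]] <- catom(head_cc, "X")
  }

  mu_attrs <- character()
  murow <- sg$cmap$mu[sg$cmap$mu$concept == head_cc, , drop = FALSE]
  if (nrow(murow) == 1L) mu_attrs <- murow$attrs[[1L]]

  sels <- lqg$selections
  for (i in seq_len(nrow(sels))) {
    ref <- sels$ref[i]; val <- sels$value[i]
    if (ref %in% mu_attrs) {
      atoms[[length(atoms) + 1L]] <- catom("@eq", c("X", val),
                                           lits = c(FALSE, TRUE),
                                           anchors = c(NA_character_, ref))
      next
    }
    arow <- filter(sg$rmap, .data$ref_b == ref, .data$category != "unmapped")
    if (nrow(arow) > 0L) {
      anm <- sort_c(unique(arow$association))[1L]
      atoms[[length(atoms) + 1L]] <- catom(anm, c("X", val),
                                           lits = c(FALSE, TRUE),
                                           anchors = c(NA_character_, ref))
    } else {
      atoms[[length(atoms) + 1L]] <- catom("@prop", c("X", val),
                                           lits = c(FALSE, TRUE),
                                           anchors = c(NA_character_, ref))
    }
  }

  # secondary roles with concept heads get their own variable; verbs (or a
  # structural path link) relate them to the answer variable
  terms <- lqg$terminals
  verb_rows <- terms[terms$part == "verb", , drop = FALSE]
  role_vars <- c(`1` = "X")
  role_heads <- terms[terms$part == "head" & startsWith(terms$node, "concept:"), ,
                      drop = FALSE]
  for (i in seq_len(nrow(role_heads))) {
    rid <- role_heads$role_id[i]
    if (is.na(rid) || rid == 1L) next
    v <- paste0("V", rid)
    cc <- sub("^concept:", "", role_heads$node[i])
    role_vars[as.character(rid)] <- v
    var_concepts[v] <- cc
    atoms[[length(atoms) + 1L]] <- catom(cc, v)
    linked <- FALSE
    if (nrow(verb_rows) > 0L) {
      anm <- sub("^assoc:", "", verb_rows$node[1L])
      atoms[[length(atoms) + 1L]] <- catom(anm, c("X", v))
      linked <- TRUE
    }
    if (!linked) {
      atoms[[length(atoms) + 1L]] <- catom("@path", c("X", v))
    }
  }
  list(atoms = atoms, var_concepts = var_concepts)
}

#' Cooperatively expand a logical query graph with inference rules
#'
#' Standard Datalog-style unfolding: an atom whose predicate heads one or
#' more rules is replaced by each rule's body (head variables unify with
#' the atom's arguments, other body variables are renamed fresh),
#' producing alternative derivations of the same question.  The base
#' derivation (depth 0) is always first; expansion is breadth-first by
#' depth, deterministic, halts at `max_depth` regardless of rule
#' recursion, and removes duplicates modulo variable renaming.
#' Undefined predicates introduced by rule bodies (e.g. ortholog,
#' homolog) stay symbolic here; SQL generation grounds them against value
#' mappings or registered functions.
#'
#' @param lqg a [connect_matches()] + [attach_constraints()] result.
#' @param sg the schema graph.
#' @param max_depth maximum number of rule applications (default 2, enough
#'   to reach function <- alias <- ortholog chains).
#' @return a tibble of class `coop_derivations`: `derivation_id`, `depth`,
#'   `rules_applied` (list), `atoms` (list), `label`.
#' @export
expand_derivations <- function(lqg, sg, max_depth = 2L) {
  if (max_depth < 0L) {
    stop_coop("max_depth must be non-negative", "parameter_error")
  }
  base <- lqg_to_atoms(lqg, sg)
  rules <- sg$ontology$rules
  derivs <- list(list(atoms = base$atoms, rules_applied = character(),
                      depth = 0L))
  seen <- canon_atoms(base$atoms)
  frontier <- derivs
  fresh <- 0L
  for (d in seq_len(max_depth)) {
    nxt <- list()
    for (deriv in frontier) {
      for (ai in seq_along(deriv$atoms)) {
        a <- deriv$atoms[[ai]]
        if (startsWith(a$predicate, "@")) next
        for (rl in rules) {
          if (rl$head$predicate != a$predicate ||
              rl$head$arity != length(a$args)) next
          # unify: head variables bind to the atom's argument slots
          bind <- stats::setNames(seq_along(rl$head$args), rl$head$args)
          body <- map(rl$body, function(b) {
            args <- character(length(b$args))
            lits <- logical(length(b$args))
            anchors <- rep(NA_character_, length(b$args))
            for (k in seq_along(b$args)) {
              arg <- b$args[k]
              if (is_rule_var(arg) && arg %in% names(bind)) {
                slot <- bind[[arg]]
                args[k] <- a$args[slot]; lits[k] <- a$lits[slot]
                anchors[k] <- a$anchors[slot]
              } else if (is_rule_var(arg)) {
                args[k] <- paste0("Z", arg, "_", fresh)
              } else {
                args[k] <- gsub("^'|'$", "", arg); lits[k] <- TRUE
              }
            }
            catom(b$predicate, args, lits, anchors)
          })
          fresh <- fresh + 1L
          new_atoms <- c(deriv$atoms[seq_len(ai - 1L)], body,
                         deriv$atoms[-seq_len(ai)])
          key <- canon_atoms(new_atoms)
          if (key %in% seen) next
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- list(
            atoms = new_atoms,
            rules_applied = c(deriv$rules_applied, rl$rule_id),
            depth = d)
        }
      }
    }
    if (length(nxt) == 0L) break
    ord <- order(map_chr(nxt, function(x) paste(x$rules_applied, collapse = ",")),
                 method = "radix")
    nxt <- nxt[ord]
    derivs <- c(derivs, nxt)
    frontier <- nxt
  }
  out <- tibble(
    derivation_id = paste0("d", seq_along(derivs)),
    depth = map_int(derivs, "depth"),
    rules_applied = map(derivs, "rules_applied"),
    atoms = map(derivs, "atoms"),
    label = map_chr(derivs, function(x) atoms_text(x$atoms)))
  attr(out, "var_concepts") <- base$var_concepts
  attr(out, "lqg") <- lqg
  class(out) <- c("coop_derivations", class(out))
  out
}

#' @export
print.coop_derivations <- function(x, ...) {
  cat("<coop_derivations> ", nrow(x), " derivation(s), max depth ",
      max(x$depth), "\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat("  ", x$derivation_id[i], " [depth ", x$depth[i],
        if (length(x$rules_applied[[i]]) > 0L)
          paste0(", rules ", paste(x$rules_applied[[i]], collapse = "+")),
        "]: ", x$label[i], "\n", sep = "")
  }
  invisible(x)
}

#' @rdname expand_derivations
#' @param x a `coop_derivations` tibble.
#' @param ... unused.
#' @method tidy coop_derivations
#' @export
tidy.coop_derivations <- function(x, ...) {
  tibble(derivation_id = x$derivation_id, depth = x$depth,
         n_rules = map_int(x$rules_applied, length),
         rules = map_chr(x$rules_applied, paste, collapse = "+"),
         label = x$label)
}
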