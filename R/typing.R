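#' Construct a term/value lexicon
#'
#' One table drives both column-value typing and query-term analysis.
#' Columns: `surface` (lower-cased form as it appears in values or
#' queries), `lemma` (base form), `pos` (part of speech for the query
#' parser: noun, propn, verb, adj, det, prep, aux), `type` (type-hierarchy
#' node the value belongs to, or `NA` for pure grammar entries) and
#' `canonical` (the cased form stored in the database instance, used when
#' the term becomes a selection literal).
#'
#' @param df a data frame with (a subset of) those columns.
#' @return a tibble of class `coop_lexicon`.
#' @export
lexicon <- function(df) {
  df <- as_tibble(df)
  for (col in c("surface", "lemma", "pos", "type", "canonical")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$surface <- str_to_lower(df$surface)
  df$lemma <- ifelse(is.na(df$lemma), df$surface, str_to_lower(df$lemma))
  class(df) <- c("coop_lexicon", class(df))
  df
}

#' Read a lexicon from a TSV file
#'
#' @param path a tab-separated file with a header row naming any of the
#'   [lexicon()] columns.
#' @return a `coop_lexicon` tibble.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop_coop(paste0("lexicon file not found: ", path), "io_error")
  lexicon(utils::read.delim(path, colClasses = "character", check.names = FALSE,
                            na.strings = c("NA", "")))
}

#' Write a lexicon to a TSV file
#' @param x a `coop_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(x, path) {
  utils::write.table(as.data.frame(x)[, c("surface", "lemma", "pos", "type", "canonical")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# Syntactic value-typing: lexicon lookup first, then shape rules.  Shape
# rules only fire when their target type exists in the hierarchy, so
# generated worlds are free to use a disjoint type vocabulary (their
# values carry an explicit "type::n" tag).
type_value <- function(values, lex, th) {
  vals <- as.character(values)
  low <- str_to_lower(str_trim(vals))
  out <- rep(NA_character_, length(vals))

  lex_types <- lex$type[match(low, lex$surface)]
  out[!is.na(lex_types)] <- lex_types[!is.na(lex_types)]

  tag <- regmatches(vals, regexec("^([a-z][a-z0-9_]*)::", vals))
  tagged <- map_chr(tag, function(m) if (length(m) == 2L) m[2] else NA_character_)
  use <- is.na(out) & !is.na(tagged) & tagged %in% th$nodes
  out[use] <- tagged[use]

  shape <- function(pattern, type) {
    if (!type %in% th$nodes) return(invisible(NULL))
    use <- is.na(out) & grepl(pattern, vals)
    out[use] <<- type
    invisible(NULL)
  }
  shape("^[0-9]+$", "gene")                       # numeric IDs read as genes
  shape("^LOC[0-9]+$", "gene")                    # LOC-style loci
  shape("^[A-Z][0-9][A-Z0-9]{3}[0-9]$", "protein")  # UniProt accessions
  shape("^[ACGTUacgtu]{10,}$", "sequence")
  shape("^[A-Z][A-Za-z0-9-]{1,9}$", "gene name")  # short symbols

  out[!nzchar(str_trim(vals)) | is.na(vals)] <- NA_character_
  out
}

#' Infer a type for every database column
#'
#' Samples up to `sample_size` distinct values per column (deterministic
#' under `seed`), types each value by lexicon lookup and syntactic shape
#' rules, and assigns the column the least upper bound of the sampled
#' value types in the hierarchy.  Columns with no typable values (or no
#' rows) are typed as the hierarchy root, with a logged note.
#'
#' @param db a [database()].
#' @param th a [type_hierarchy()].
#' @param lex a [lexicon()].
#' @param sample_size maximum distinct values inspected per column.
#' @param seed integer seed making the sample reproducible.
#' @return a tibble with columns `relation`, `attribute`, `ref`, `type`,
#'   `n_sampled`.
#' @export
infer_attribute_types <- function(db, th, lex, sample_size = 100L, seed = 1L) {
  refs <- attribute_refs(db)
  rows <- pmap(list(refs$relation, refs$attribute, refs$ref), function(rel, att, ref) {
    vals <- sort_c(unique(compact_chr(db$tables[[rel]][[att]])))
    if (length(vals) > sample_size) {
      vals <- local_sample(vals, sample_size, seed = seed + nchar(ref))
    }
    types <- compact_chr(unique(type_value(vals, lex, th)))
    if (length(types) == 0L) {
      coop_log("column ", ref, " has no typable values; typed as root")
      ty <- th$root
    } else {
      ty <- type_lub(types, th)
    }
    tibble(relation = rel, attribute = att, ref = ref, type = ty,
           n_sampled = length(vals))
  })
  bind_rows(rows)
}

# draw k of x reproducibly without touching the caller's RNG state
local_sample <- function(x, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sort_c(sample(x, k))
}
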