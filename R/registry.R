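#' External function registry
#'
#' External resources (identifier mappers, organism lookups, sequence
#' homology checks) enter the pipeline as typed functions: each has a
#' name, input concept/type identifiers, an output concept/type
#' identifier, and an implementation.  Mock implementations are closures
#' over bundled lookup tables; `mode = "live"` entries keep the same
#' contract but refuse to run, so test suites only ever exercise mocks.
#' Calls are memoized; unknown inputs return `NA` (the SQL layer treats
#' `NA` as a failed predicate).
#'
#' @param ... entries created with [registry_function()].
#' @return an object of class `coop_registry`.
#' @export
function_registry <- function(...) {
  entries <- list(...)
  names(entries) <- map_chr(entries, "name")
  structure(list(functions = entries, memo = new.env(parent = emptyenv())),
            class = "coop_registry")
}

#' Declare one registry entry
#'
#' @param name function name as it appears in generated SQL.
#' @param inputs character vector of input concept/type identifiers.
#' @param output output concept/type identifier.
#' @param fn implementation: takes `length(inputs)` character scalars,
#'   returns a character scalar or `NA`.  Ignored when `mode = "live"`.
#' @param mode `"mock"` or `"live"`.
#' @param params named list of settings (e.g. a homology threshold).
#' @return a registry entry (plain list).
#' @export
registry_function <- function(name, inputs, output, fn = NULL, mode = "mock",
                              params = list()) {
  if (mode == "mock" && !is.function(fn)) {
    stop_coop(paste0("mock function '", name, "' needs an implementation"),
              "registry_error")
  }
  list(name = name, inputs = inputs, output = output, fn = fn, mode = mode,
       params = params)
}

#' Add an entry to a registry
#' @param reg a [function_registry()].
#' @param entry a [registry_function()].
#' @return the updated registry.
#' @export
register_function <- function(reg, entry) {
  reg$functions[[entry$name]] <- entry
  reg
}

#' Call a registered external function
#'
#' @param reg a [function_registry()].
#' @param name registered function name.
#' @param ... arguments (character scalars), matching the declared arity.
#' @param memoize reuse cached results for repeated identical calls.
#' @return a character scalar, or `NA` for unknown inputs.
#' @export
call_function <- function(reg, name, ..., memoize = TRUE) {
  entry <- reg$functions[[name]]
  if (is.null(entry)) {
    stop_coop(paste0("function '", name, "' is not registered"), "registry_error")
  }
  args <- as.character(c(...))
  if (length(args) != length(entry$inputs)) {
    stop_coop(paste0("function '", name, "' expects ", length(entry$inputs),
                     " argument(s), got ", length(args)), "registry_error")
  }
  if (entry$mode == "live") {
    stop_coop(paste0("function '", name,
                     "' is registered as live and is disabled in this session"),
              "registry_error")
  }
  key <- paste(c(name, args), collapse = "\r")
  if (memoize && !is.null(reg$memo[[key]])) return(reg$memo[[key]])
  val <- entry$fn(args)
  val <- if (is.null(val) || length(val) == 0L) NA_character_ else as.character(val)[1L]
  if (memoize) reg$memo[[key]] <- val
  val
}

# lookup-table mock: named-list style table keyed on "\r"-joined arguments
table_mock <- function(tbl) {
  force(tbl)
  function(args) {
    key <- paste(args, collapse = "\r")
    tbl[[key]] %||% NA_character_
  }
}

mock_table_key <- function(...) paste(c(...), collapse = "\r")

#' Fraction of identical aligned positions between two sequences
#'
#' A deliberately simple stand-in for a full homology search: the two
#' sequences are compared position by position (no gaps) and the identity
#' fraction uses the longer length as denominator, so it lies in
#' `[0, 1]`.
#'
#' @param s1,s2 character scalars (e.g. DNA strings).
#' @return a number in `[0, 1]`.
#' @export
sequence_identity <- function(s1, s2) {
  a <- strsplit(as.character(s1), "")[[1]]
  b <- strsplit(as.character(s2), "")[[1]]
  if (length(a) == 0L || length(b) == 0L) return(0)
  n <- min(length(a), length(b))
  sum(a[seq_len(n)] == b[seq_len(n)]) / max(length(a), length(b))
}

#' Read a function registry from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `inputs`,
#' `output`, `mode` (`mock`/`live`), and for mocks `table` — a path
#' (relative to the config file) to a TSV whose first columns are the
#' argument values and whose last column is the returned value.
#'
#' @param path JSON config path.
#' @return a [function_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop_coop(paste0("registry config not found: ", path), "io_error")
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- function_registry()
  for (entry in cfg) {
    if (identical(entry$mode, "live")) {
      reg <- register_function(reg, registry_function(
        name = entry$name, inputs = unlist(entry$inputs),
        output = entry$output, mode = "live"))
      next
    }
    tsv <- file.path(dirname(path), entry$table)
    df <- utils::read.delim(tsv, colClasses = "character", check.names = FALSE)
    narg <- ncol(df) - 1L
    tbl <- stats::setNames(
      as.list(df[[ncol(df)]]),
      apply(df[, seq_len(narg), drop = FALSE], 1L, paste, collapse = "\r"))
    reg <- register_function(reg, registry_function(
      name = entry$name, inputs = unlist(entry$inputs), output = entry$output,
      fn = table_mock(tbl), mode = "mock"))
  }
  reg
}
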