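#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr filter mutate select arrange left_join inner_join bind_rows
#'   distinct group_by summarise ungroup rename pull across all_of n
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_lgl map_int map2 pmap keep discard compact
#' @importFrom stringr str_trim str_detect str_replace str_split str_to_lower
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# classed condition helpers -- every user-facing failure mode carries a
# coopquery_* class so callers (and the CLI) can branch on it
stop_coop <- function(msg, class, ...) {
  abort(msg, class = c(paste0("coopquery_", class), "coopquery_error"), ...)
}

is_named_list <- function(x) is.list(x) && !is.null(names(x)) || (is.list(x) && length(x) == 0L)

# deterministic lexicographic sort independent of locale
sort_c <- function(x) {
  if (length(x) == 0L) return(x)
  x[order(method = "radix", x)]
}

compact_chr <- function(x) x[!is.na(x) & nzchar(x)]

`%or%` <- function(a, b) if (length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
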