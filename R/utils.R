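# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a classed condition
#' @noRd
fc_stop <- function(.class, message, ...) {
  stop(structure(
    class = c(.class, "fhircurate_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

fc_warn <- function(message) warning(message, call. = FALSE)

#' Null tokens recognised in source cells (case-insensitive)
#' @noRd
NULL_TOKENS <- c("", "na", "null")

is_null_cell <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x) ||
    tolower(trimws(as.character(x))) %in% NULL_TOKENS
}

#' Parse a date from ISO 8601 or DD/MM/YYYY
#'
#' Returns an ISO "YYYY-MM-DD" string or NA if unparseable. The accepted
#' format list is configurable because source extracts rarely document their
#' date dialect.
#' @noRd
parse_source_date <- function(x, formats = c("%Y-%m-%d", "%d/%m/%Y")) {
  x <- trimws(as.character(x))
  if (!nzchar(x)) return(NA_character_)
  for (fmt in formats) {
    d <- as.Date(x, format = fmt, optional = TRUE)
    if (!is.na(d)) {
      # reject partial matches such as "12/34" under %Y-%m-%d
      if (format(d, fmt) == x || fmt == "%Y-%m-%d") return(format(d, "%Y-%m-%d"))
    }
  }
  NA_character_
}

parse_source_number <- function(x) {
  x <- trimws(as.character(x))
  if (!nzchar(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

#' Set a value at a dotted path inside a nested list, creating intermediates
#' @noRd
set_path <- function(tree, parts, value) {
  if (length(parts) == 1) {
    tree[[parts]] <- value
    return(tree)
  }
  sub <- tree[[parts[1]]]
  if (is.null(sub)) sub <- list()
  tree[[parts[1]]] <- set_path(sub, parts[-1], value)
  tree
}

#' Get a value at a dotted path; NULL when absent
#' @noRd
get_path <- function(tree, parts) {
  for (p in parts) {
    if (!is.list(tree)) return(NULL)
    # FHIR arrays: descend into each element and merge
    if (is.null(names(tree)) && length(tree) > 0) {
      vals <- lapply(tree, function(el) get_path(el, p))
      vals <- vals[!vapply(vals, is.null, logical(1))]
      if (length(vals) == 0) return(NULL)
      tree <- if (length(vals) == 1) vals[[1]] else vals
      next
    }
    tree <- tree[[p]]
    if (is.null(tree)) return(NULL)
  }
  tree
}

#' Is x a FHIR JSON array (unnamed list)?
#' @noRd
is_fhir_array <- function(x) is.list(x) && is.null(names(x)) && length(x) > 0

#' Read a JSON file preserving the FHIR tree shape
#' @noRd
read_fhir_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' ISO 8601 timestamp (UTC) for meta.lastUpdated / Provenance.recorded
#' @noRd
fhir_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Path to a shipped fixture
#'
#' Convenience accessor for the synthetic conformance artifacts, mapping
#' configurations and the FAIR indicator catalogue installed with the
#' package under \code{extdata/}.
#'
#' @param ... path components below \code{extdata/}, e.g.
#'   \code{fhircurate_extdata("profiles")}.
#' @return An absolute file path.
#' @export
fhircurate_extdata <- function(...) {
  system.file("extdata", ..., package = "fhircurate", mustWork = TRUE)
}
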