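# Local structural validation of resource instances against a flattened
# profile: cardinality, primitive datatypes, required value-set bindings and
# fixed values. A remote $validate passthrough can be plugged in at the
# session level; local validation always runs first for path-precise
# diagnostics.

FHIR_ID_REGEX <- "^[A-Za-z0-9.-]{1,64}$"

valid_primitive <- function(v, type) {
  if (is.list(v)) return(FALSE)
  if (length(v) != 1 || is.na(v)) return(FALSE)
  switch(type,
    boolean = is.logical(v) || v %in% c("true", "false"),
    integer = ,
    positiveInt = ,
    unsignedInt = grepl("^[+-]?[0-9]+$", as.character(v)),
    decimal = !is.na(suppressWarnings(as.numeric(v))),
    date = grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", as.character(v)),
    dateTime = ,
    instant = grepl(
      "^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:\\d{2})?)?)?)?$",
      as.character(v)),
    id = grepl(FHIR_ID_REGEX, as.character(v)),
    TRUE  # string-like primitives accept any scalar
  )
}

#' Extract the coded values carried by an element value
#'
#' Understands code primitives, Coding, CodeableConcept and arrays thereof.
#' Returns a character vector of codes (possibly empty).
#' @noRd
extract_codes <- function(value) {
  if (is.null(value)) return(character(0))
  if (!is.list(value)) return(as.character(value))
  if (is_fhir_array(value)) {
    return(unlist(lapply(value, extract_codes), use.names = FALSE))
  }
  if (!is.null(value$coding)) return(extract_codes(value$coding))
  if (!is.null(value$code) && !is.list(value$code)) {
    return(as.character(value$code))
  }
  character(0)
}

check_complex_type <- function(value, type, path, add) {
  tab <- FHIR_DATATYPES[[type]]
  if (is.null(tab) || !is.list(value)) return(invisible())
  if (is_fhir_array(value)) {
    for (el in value) check_complex_type(el, type, path, add)
    return(invisible())
  }
  for (nm in intersect(names(value), names(tab))) {
    sub_type <- tab[[nm]]
    sub_path <- paste0(path, ".", nm)
    if (sub_type %in% PRIMITIVE_TYPES) {
      vals <- if (is_fhir_array(value[[nm]])) value[[nm]] else list(value[[nm]])
      for (v in vals) {
        if (!valid_primitive(v, sub_type)) {
          add("wrong-type", sub_path, "error", sprintf(
            "value '%s' is not a valid %s", paste(format(v), collapse = " "),
            sub_type))
        }
      }
    } else {
      check_complex_type(value[[nm]], sub_type, sub_path, add)
    }
  }
}

values_match <- function(a, b) {
  if (is.list(a) != is.list(b)) return(FALSE)
  if (!is.list(a)) return(identical(as.character(a), as.character(b)))
  isTRUE(all.equal(a[order(names(a))], b[order(names(b))]))
}

#' Validate a resource instance against a profile
#'
#' Checks, for every constraint in the flattened profile:
#' \itemize{
#'   \item \code{cardinality-min}: a min >= 1 element is unpopulated (nested
#'     requirements fire only when their parent element is populated);
#'   \item \code{cardinality-max}: an array exceeds the bounded max;
#'   \item \code{wrong-type}: a primitive value does not parse as its
#'     declared FHIR datatype (descending shallowly into common complex
#'     datatypes such as Quantity and CodeableConcept);
#'   \item \code{binding}: a coded value is not a member of the bound value
#'     set — enforced (error) for \code{required} bindings, advisory
#'     (warning) for extensible/preferred/example ones, and degraded to a
#'     warning when the value set is not locally loaded;
#'   \item \code{fixed-mismatch}: a populated value differs from the
#'     profile's fixed value.
#' }
#'
#' @param resource A FHIR resource JSON tree (named list with
#'   \code{resourceType}).
#' @param profile The matching \code{fhir_profile}.
#' @param valuesets Named list of code vectors keyed by value-set canonical
#'   URL, e.g. from \code{\link{load_valuesets}}.
#' @return A data.frame of violations with columns \code{path}, \code{code},
#'   \code{severity}, \code{detail}; zero rows when the resource conforms.
#' @export
validate_resource <- function(resource, profile, valuesets = list()) {
  stopifnot(inherits(profile, "fhir_profile"))
  if (!identical(resource$resourceType, profile$resource_type)) {
    fc_stop("precondition", sprintf(
      "resource is a %s but profile defines %s",
      resource$resourceType %||% "<missing resourceType>", profile$resource_type))
  }
  out <- list()
  add <- function(code, path, severity, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      path = path, code = code, severity = severity, detail = detail,
      stringsAsFactors = FALSE)
  }

  cs <- profile$constraints
  root <- profile$resource_type
  for (i in seq_len(nrow(cs))) {
    path <- cs$path[i]
    if (path == root) next
    parts <- strsplit(substring(path, nchar(root) + 2), ".", fixed = TRUE)[[1]]
    value <- get_path(resource, parts)

    if (is.null(value)) {
      if (cs$min[i] >= 1) {
        parent_ok <- length(parts) == 1 ||
          !is.null(get_path(resource, parts[-length(parts)]))
        if (parent_ok) {
          add("cardinality-min", path, "error",
              sprintf("required element %s is not populated", path))
        }
      }
      next
    }

    n_vals <- if (is_fhir_array(value)) length(value) else 1L
    if (is.finite(cs$max[i]) && n_vals > cs$max[i]) {
      add("cardinality-max", path, "error", sprintf(
        "%d repetition(s) exceed max cardinality %d", n_vals, cs$max[i]))
    }

    types <- cs$types[[i]]
    if (length(types) >= 1) {
      tp <- types[[1]]
      if (tp %in% PRIMITIVE_TYPES) {
        vals <- if (is_fhir_array(value)) value else list(value)
        for (v in vals) {
          if (!valid_primitive(v, tp)) {
            add("wrong-type", path, "error", sprintf(
              "value '%s' is not a valid %s",
              paste(format(v), collapse = " "), tp))
          }
        }
      } else {
        check_complex_type(value, tp, path, add)
      }
    }

    strength <- cs$binding_strength[i]
    if (!is.na(strength) && nzchar(strength)) {
      vs_url <- cs$binding_valueset[i]
      codes <- extract_codes(value)
      if (length(codes) > 0) {
        vs <- valuesets[[vs_url]]
        if (is.null(vs)) {
          if (identical(strength, "required")) {
            add("binding", path, "warning", sprintf(
              "value set %s is not loaded; membership of '%s' not checked",
              vs_url, paste(codes, collapse = ",")))
          }
        } else {
          outside <- setdiff(codes, vs)
          if (length(outside) > 0) {
            sev <- if (identical(strength, "required")) "error" else "warning"
            add("binding", path, sev, sprintf(
              "code '%s' is not in value set %s (%s binding)",
              paste(outside, collapse = ","), vs_url, strength))
          }
        }
      }
    }

    fixed <- cs$fixed[[i]]
    if (!is.null(fixed) && !values_match(value, fixed)) {
      add("fixed-mismatch", path, "error", sprintf(
        "value at %s differs from the profile's fixed value", path))
    }
  }

  if (length(out) == 0) {
    return(data.frame(path = character(0), code = character(0),
                      severity = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Do the violations block persistence?
#'
#' Only error-severity violations gate persistence; warnings are advisory.
#' @param violations Result of \code{\link{validate_resource}}.
#' @return TRUE when any error-severity violation is present.
#' @export
has_blocking_violation <- function(violations) {
  nrow(violations) > 0 && any(violations$severity == "error")
}

#' Load ValueSet / CodeSystem fixtures into code membership tables
#'
#' Reads all \code{.json} files under \code{dir}. CodeSystems contribute
#' their concept codes; ValueSets contribute expansion contents or
#' compose.include concepts, falling back to the full concept list of an
#' included CodeSystem loaded from the same directory.
#'
#' @param dir Directory of FHIR R4 ValueSet/CodeSystem JSON files.
#' @return Named list: value-set canonical URL -> character vector of codes.
#' @export
load_valuesets <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  docs <- lapply(files, read_fhir_json)
  systems <- list()
  for (d in docs) {
    if (identical(d$resourceType, "CodeSystem")) {
      systems[[d$url]] <- vapply(d$concept %||% list(),
                                 function(c) as.character(c$code), "")
    }
  }
  out <- list()
  for (d in docs) {
    if (!identical(d$resourceType, "ValueSet")) next
    codes <- character(0)
    for (cont in d$expansion$contains %||% list()) {
      codes <- c(codes, as.character(cont$code))
    }
    for (inc in d$compose$include %||% list()) {
      if (length(inc$concept %||% list()) > 0) {
        codes <- c(codes, vapply(inc$concept, function(c) as.character(c$code), ""))
      } else if (!is.null(inc$system) && !is.null(systems[[inc$system]])) {
        codes <- c(codes, systems[[inc$system]])
      }
    }
    out[[d$url]] <- unique(codes)
  }
  out
}
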