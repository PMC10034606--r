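# Conformance-artifact parsing: CapabilityStatement and StructureDefinition
# snapshots are flattened into a queryable constraint model that drives both
# mapping checks and local validation.

#' Parse a CapabilityStatement into server capabilities
#'
#' Reads a FHIR R4 \code{CapabilityStatement} JSON tree and extracts, for
#' every \code{rest.resource} entry, the resource type, its supported
#' profiles (canonical URLs) and the supported interactions. When a resource
#' entry lists no \code{supportedProfile}, the caller is expected to fall
#' back to the base resource definition.
#'
#' @param doc A parsed JSON tree (nested list) with
#'   \code{resourceType == "CapabilityStatement"}.
#' @return An object of class \code{fhir_capabilities}: a list with
#'   \code{fhir_version} and \code{resource_entries}, the latter a named list
#'   (by resource type) of \code{list(resource_type, supported_profiles,
#'   interactions)}.
#' @examples
#' doc <- list(resourceType = "CapabilityStatement", fhirVersion = "4.0.1",
#'             rest = list(list(mode = "server", resource = list())))
#' parse_capability_statement(doc)
#' @export
parse_capability_statement <- function(doc) {
  if (!is.list(doc) || !identical(doc$resourceType, "CapabilityStatement")) {
    fc_stop("malformed_conformance",
            "document is not a CapabilityStatement resource")
  }
  entries <- list()
  rest <- doc$rest
  if (is.null(rest) || length(rest) == 0) {
    fc_warn("CapabilityStatement has no rest section; capabilities are empty")
  } else {
    for (r in rest) {
      for (res in r$resource %||% list()) {
        type <- res$type
        if (is.null(type)) next
        if (!is.null(entries[[type]])) {
          fc_stop("malformed_conformance",
                  sprintf("duplicate rest.resource entry for type '%s'", type))
        }
        profiles <- vapply(res$supportedProfile %||% list(), as.character, "")
        interactions <- vapply(res$interaction %||% list(),
                               function(i) as.character(i$code %||% ""), "")
        interactions <- unique(interactions[nzchar(interactions)])
        entries[[type]] <- list(
          resource_type = type,
          supported_profiles = as.character(profiles),
          interactions = interactions
        )
      }
    }
  }
  structure(
    list(fhir_version = doc$fhirVersion %||% NA_character_,
         resource_entries = entries),
    class = "fhir_capabilities"
  )
}

#' @export
print.fhir_capabilities <- function(x, ...) {
  cat("<fhir_capabilities> FHIR", x$fhir_version, "-",
      length(x$resource_entries), "resource type(s)\n")
  for (e in x$resource_entries) {
    cat(sprintf("  %-20s profiles: %d  interactions: %s\n", e$resource_type,
                length(e$supported_profiles),
                paste(e$interactions, collapse = ",")))
  }
  invisible(x)
}

#' Supported profiles for a resource type
#' @param caps A \code{fhir_capabilities} object.
#' @param resource_type Resource type name, e.g. \code{"Patient"}.
#' @return Character vector of canonical URLs (empty when the server lists
#'   none, meaning the base definition applies).
#' @export
supported_profiles <- function(caps, resource_type) {
  stopifnot(inherits(caps, "fhir_capabilities"))
  e <- caps$resource_entries[[resource_type]]
  if (is.null(e)) character(0) else e$supported_profiles
}

#' Flatten a StructureDefinition snapshot into a constraint model
#'
#' Every snapshot element becomes one or more element constraints carrying
#' cardinality, datatype codes, binding (strength and value-set URL), fixed
#' values and reference targets. Choice elements (paths ending in
#' \code{"[x]"}) are expanded into one constraint per declared type with the
#' type-suffixed path, e.g. \code{Observation.value[x]} with types
#' \code{Quantity} and \code{CodeableConcept} yields
#' \code{Observation.valueQuantity} and \code{Observation.valueCodeableConcept}.
#'
#' Only snapshot-bearing StructureDefinitions are accepted; differential
#' merging against a base is out of scope. Slice names are ignored: sliced
#' elements contribute under their unsliced path (first occurrence wins).
#'
#' @param profile A parsed StructureDefinition JSON tree with a
#'   \code{snapshot.element} list.
#' @return An object of class \code{fhir_profile}: a list with
#'   \code{canonical_url}, \code{resource_type} and \code{constraints}, a
#'   data.frame with columns \code{path}, \code{min}, \code{max} (numeric;
#'   \code{Inf} for unbounded), \code{binding_strength}, \code{binding_valueset}
#'   and list-columns \code{types}, \code{fixed}, \code{ref_targets}.
#' @export
build_constraint_tree <- function(profile) {
  if (!is.list(profile) || !identical(profile$resourceType, "StructureDefinition")) {
    fc_stop("unsupported_profile", "document is not a StructureDefinition")
  }
  elements <- profile$snapshot$element
  if (is.null(elements) || length(elements) == 0) {
    fc_stop("unsupported_profile",
            "StructureDefinition has no snapshot; differential-only profiles are not supported")
  }
  resource_type <- profile$type %||% strsplit(elements[[1]]$path, ".", fixed = TRUE)[[1]][1]

  rows <- list()
  for (el in elements) {
    path <- el$path
    if (is.null(path)) next
    min <- as.integer(el$min %||% 0L)
    max_raw <- el$max %||% "*"
    max <- if (identical(max_raw, "*")) Inf else as.numeric(max_raw)
    types <- vapply(el$type %||% list(), function(t) as.character(t$code %||% ""), "")
    types <- types[nzchar(types)]
    ref_targets <- character(0)
    if ("Reference" %in% types) {
      for (t in el$type) {
        if (identical(t$code, "Reference")) {
          tp <- vapply(t$targetProfile %||% list(), as.character, "")
          ref_targets <- sub("^.*StructureDefinition/", "", tp)
        }
      }
    }
    strength <- el$binding$strength %||% NA_character_
    vs <- el$binding$valueSet %||% NA_character_
    if (identical(strength, "required") && (is.na(vs) || !nzchar(vs))) {
      fc_stop("unsupported_profile",
              sprintf("required binding without a value set URL at %s", path))
    }
    fixed <- NULL
    fixed_keys <- grep("^fixed", names(el), value = TRUE)
    if (length(fixed_keys) > 0) fixed <- el[[fixed_keys[1]]]

    expand <- if (grepl("\\[x\\]$", path) && length(types) > 0) {
      vapply(types, function(tc) {
        sub("\\[x\\]$", paste0(toupper(substring(tc, 1, 1)), substring(tc, 2)), path)
      }, "")
    } else path

    for (i in seq_along(expand)) {
      p <- expand[[i]]
      if (!is.null(rows[[p]])) next  # sliced re-declaration: unsliced path, first wins
      tcodes <- if (length(expand) > 1) types[[i]] else types
      rows[[p]] <- list(path = p, min = min, max = max, types = tcodes,
                        binding_strength = strength, binding_valueset = vs,
                        fixed = fixed, ref_targets = ref_targets)
    }
  }

  constraints <- data.frame(
    path = vapply(rows, `[[`, "", "path"),
    min = vapply(rows, `[[`, 0L, "min"),
    max = vapply(rows, `[[`, 0, "max"),
    binding_strength = vapply(rows, `[[`, "", "binding_strength"),
    binding_valueset = vapply(rows, `[[`, "", "binding_valueset"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  constraints$types <- unname(lapply(rows, `[[`, "types"))
  constraints$fixed <- unname(lapply(rows, `[[`, "fixed"))
  constraints$ref_targets <- unname(lapply(rows, `[[`, "ref_targets"))

  bad <- constraints$min > constraints$max
  if (any(bad)) {
    fc_stop("unsupported_profile",
            sprintf("min > max at %s", constraints$path[bad][1]))
  }
  structure(
    list(canonical_url = profile$url %||% NA_character_,
         resource_type = resource_type,
         constraints = constraints),
    class = "fhir_profile"
  )
}

#' @export
print.fhir_profile <- function(x, ...) {
  req <- sum(x$constraints$min >= 1)
  cat("<fhir_profile>", x$resource_type, "-", nrow(x$constraints),
      "constraint(s),", req, "required\n")
  cat("  url:", x$canonical_url, "\n")
  invisible(x)
}

#' Required element paths of a profile
#'
#' Paths with minimum cardinality >= 1, excluding the resource root.
#' @param profile A \code{fhir_profile}.
#' @return Character vector of dotted paths.
#' @export
required_paths <- function(profile) {
  stopifnot(inherits(profile, "fhir_profile"))
  cs <- profile$constraints
  setdiff(cs$path[cs$min >= 1], profile$resource_type)
}

#' Load all profiles from a directory of StructureDefinition JSON files
#'
#' One resource per \code{.json} file. Non-StructureDefinition files are
#' skipped with a warning.
#'
#' @param dir Directory path.
#' @return Named list of \code{fhir_profile} objects keyed by canonical URL.
#' @export
load_profiles <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  out <- list()
  for (f in files) {
    doc <- read_fhir_json(f)
    if (!identical(doc$resourceType, "StructureDefinition")) next
    p <- build_constraint_tree(doc)
    out[[p$canonical_url]] <- p
  }
  out
}

#' Look up a profile for a resource mapping
#'
#' Prefers the mapping's explicit profile URL; otherwise the first loaded
#' profile whose resource type matches.
#' @noRd
find_profile <- function(profiles, resource_type, profile_url = NULL) {
  if (!is.null(profile_url) && !is.na(profile_url) && nzchar(profile_url)) {
    p <- profiles[[profile_url]]
    if (is.null(p)) {
      fc_stop("unsupported_profile",
              sprintf("profile %s is not loaded", profile_url))
    }
    return(p)
  }
  for (p in profiles) if (identical(p$resource_type, resource_type)) return(p)
  fc_stop("unsupported_profile",
          sprintf("no profile loaded for resource type %s", resource_type))
}
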