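# Embedded minimal FHIR repository: in-memory, versioned, validating on
# write, with a practical search subset. The engine talks to it through the
# same call contract it would use against a remote server, so a real
# repository can be swapped in behind the same functions.

#' Create an embedded FHIR store
#'
#' An in-memory FHIR R4 repository supporting create-or-update keyed by
#' resource id (re-puts bump \code{meta.versionId}), read of the latest
#' version, soft deletion (the id stays reserved and session metadata
#' remains retrievable), a search subset and CapabilityStatement
#' generation. Resources are re-validated on write against the loaded
#' profiles; invalid resources are refused.
#'
#' @param profiles Named list of \code{fhir_profile}s (by canonical URL),
#'   e.g. from \code{\link{load_profiles}}.
#' @param valuesets Named list from \code{\link{load_valuesets}}.
#' @param base_url Base URL used to mint resource URLs.
#' @return An object of class \code{fhir_store} (environment-backed).
#' @export
fhir_store <- function(profiles = list(), valuesets = list(),
                       base_url = "http://localhost:8080/fhir") {
  store <- new.env(parent = emptyenv())
  store$entries <- new.env(parent = emptyenv())
  store$profiles <- profiles
  store$valuesets <- valuesets
  store$base_url <- sub("/$", "", base_url)
  store$soft_delete <- TRUE
  class(store) <- "fhir_store"
  store
}

#' @export
print.fhir_store <- function(x, ...) {
  keys <- ls(x$entries)
  live <- sum(!vapply(keys, function(k) isTRUE(x$entries[[k]]$deleted), TRUE))
  cat("<fhir_store>", x$base_url, "-", live, "live resource(s),",
      length(x$profiles), "profile(s)\n")
  invisible(x)
}

store_key <- function(type, id) paste0(type, "/", id)

store_profile_for <- function(store, resource) {
  purl <- resource$meta$profile
  if (!is.null(purl) && length(purl) > 0) {
    p <- store$profiles[[as.character(purl[[1]])]]
    if (!is.null(p)) return(p)
  }
  for (p in store$profiles) {
    if (identical(p$resource_type, resource$resourceType)) return(p)
  }
  NULL
}

#' Validate a resource the way the store's $validate operation would
#'
#' Local structural validation against the profile loaded for the
#' resource's declared \code{meta.profile} (falling back to the store's
#' profile for the resource type). Resources of types with no loaded
#' profile pass with zero violations (base-definition fallback).
#'
#' @param store A \code{\link{fhir_store}}.
#' @param resource A FHIR resource JSON tree.
#' @return A violations data.frame as from \code{\link{validate_resource}}.
#' @export
store_validate <- function(store, resource) {
  p <- store_profile_for(store, resource)
  if (is.null(p)) {
    return(data.frame(path = character(0), code = character(0),
                      severity = character(0), detail = character(0)))
  }
  validate_resource(resource, p, store$valuesets)
}

#' Create or update a resource
#'
#' Validates, then writes as a new version of the id (version 1 on first
#' write). The stored resource carries \code{meta.versionId} and
#' \code{meta.lastUpdated}.
#'
#' @param store A \code{\link{fhir_store}}.
#' @param resource A FHIR resource JSON tree with \code{resourceType} and
#'   a valid \code{id}.
#' @return The stored resource (invisibly), with updated meta.
#' @export
store_put <- function(store, resource) {
  type <- resource$resourceType
  id <- resource$id
  if (is.null(type) || is.null(id) || !grepl(FHIR_ID_REGEX, id)) {
    fc_stop("store_rejected", "resource needs a resourceType and a valid FHIR id")
  }
  v <- store_validate(store, resource)
  if (has_blocking_violation(v)) {
    fc_stop("store_rejected",
            sprintf("invalid %s/%s refused: %s", type, id,
                    paste(v$detail[v$severity == "error"], collapse = "; ")),
            violations = v)
  }
  key <- store_key(type, id)
  prev <- store$entries[[key]]
  version <- if (is.null(prev)) 1L else prev$version_id + 1L
  resource$meta$versionId <- as.character(version)
  resource$meta$lastUpdated <- fhir_now()
  store$entries[[key]] <- list(resource = resource, version_id = version,
                               last_updated = resource$meta$lastUpdated,
                               deleted = FALSE)
  invisible(resource)
}

#' Read the latest version of a resource
#' @param store A \code{\link{fhir_store}}.
#' @param type Resource type.
#' @param id Resource id.
#' @return The resource JSON tree.
#' @export
store_get <- function(store, type, id) {
  e <- store$entries[[store_key(type, id)]]
  if (is.null(e) || isTRUE(e$deleted)) {
    fc_stop("not_found", sprintf("%s/%s not found", type, id))
  }
  e$resource
}

#' Soft-delete a resource
#'
#' The id stays reserved (a tombstone) so that identifiers remain unique
#' and session metadata (Provenance, DocumentManifest) remains retrievable
#' after data resources are gone.
#' @param store A \code{\link{fhir_store}}.
#' @param type,id Resource coordinates.
#' @return TRUE invisibly.
#' @export
store_delete <- function(store, type, id) {
  key <- store_key(type, id)
  e <- store$entries[[key]]
  if (is.null(e)) fc_stop("not_found", sprintf("%s/%s not found", type, id))
  e$deleted <- TRUE
  store$entries[[key]] <- e
  invisible(TRUE)
}

#' All live resources of a type (or all types)
#' @param store A \code{\link{fhir_store}}.
#' @param type Resource type, or NULL for everything.
#' @return List of resource JSON trees.
#' @export
store_resources <- function(store, type = NULL) {
  keys <- ls(store$entries)
  if (!is.null(type)) keys <- keys[startsWith(keys, paste0(type, "/"))]
  out <- list()
  for (k in keys) {
    e <- store$entries[[k]]
    if (!isTRUE(e$deleted)) out[[length(out) + 1L]] <- e$resource
  }
  out
}

#' The URL of a stored resource
#' @param store A \code{\link{fhir_store}}.
#' @param type,id Resource coordinates.
#' @return \code{<base>/<Type>/<id>}.
#' @export
resource_url <- function(store, type, id) {
  paste0(store$base_url, "/", type, "/", id)
}

#' Resolve a resource URL or relative reference against the store
#' @param store A \code{\link{fhir_store}}.
#' @param url Absolute \code{<base>/<Type>/<id>} or relative
#'   \code{<Type>/<id>} reference.
#' @return The resource JSON tree (errors with \code{not_found} otherwise).
#' @export
resolve_url <- function(store, url) {
  rel <- sub(paste0("^", store$base_url, "/"), "", url)
  parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) fc_stop("not_found", sprintf("unresolvable URL %s", url))
  store_get(store, parts[1], parts[2])
}

token_matches <- function(resource, field, value) {
  # "system|code" syntax; bare value matches code regardless of system
  sys <- NA_character_
  code <- value
  if (grepl("|", value, fixed = TRUE)) {
    parts <- strsplit(value, "|", fixed = TRUE)[[1]]
    sys <- parts[1]
    code <- if (length(parts) > 1) parts[2] else ""
  }
  vals <- switch(field,
    code = resource$code %||% resource$medicationCodeableConcept,
    gender = resource$gender,
    identifier = resource$identifier,
    NULL)
  if (is.null(vals)) return(FALSE)
  pairs <- coding_pairs(vals)
  any(vapply(pairs, function(p) {
    identical(p$code, code) && (is.na(sys) || identical(p$system %||% "", sys))
  }, TRUE))
}

#' Flatten an element value into (system, code) pairs
#' @noRd
coding_pairs <- function(value) {
  if (is.null(value)) return(list())
  if (!is.list(value)) return(list(list(system = NA_character_, code = as.character(value))))
  if (is_fhir_array(value)) {
    return(unlist(lapply(value, coding_pairs), recursive = FALSE))
  }
  if (!is.null(value$coding)) return(coding_pairs(value$coding))
  if (!is.null(value$code) || !is.null(value$value)) {
    code <- value$code %||% value$value
    return(list(list(system = value$system %||% NA_character_,
                     code = as.character(code))))
  }
  list()
}

resource_date <- function(resource) {
  d <- resource$effectiveDateTime %||% resource$period$start %||%
    resource$onsetDateTime %||% resource$recorded %||% NULL
  if (is.null(d)) NA_character_ else substr(as.character(d), 1, 10)
}

date_matches <- function(resource, values) {
  d <- resource_date(resource)
  if (is.na(d)) return(FALSE)
  d <- as.Date(d)
  for (v in values) {
    pref <- substr(v, 1, 2)
    if (!pref %in% c("ge", "le", "gt", "lt", "eq")) {
      pref <- "eq"
      bound <- as.Date(substr(v, 1, 10))
    } else {
      bound <- as.Date(substr(v, 3, 12))
    }
    ok <- switch(pref, ge = d >= bound, le = d <= bound, gt = d > bound,
                 lt = d < bound, eq = d == bound)
    if (!isTRUE(ok)) return(FALSE)
  }
  TRUE
}

reference_matches <- function(resource, field, value) {
  ref <- resource[[field]]$reference
  if (is.null(ref)) return(FALSE)
  identical(ref, value) || endsWith(ref, paste0("/", value))
}

SUPPORTED_SEARCH_PARAMS <- c("_id", "_count", "code", "gender", "identifier",
                             "date", "subject", "encounter")

#' Search the store
#'
#' Supported parameters: \code{_id}; token search on \code{code} (Condition
#' and Observation codes, MedicationStatement medication), \code{gender}
#' and \code{identifier} with \code{system|code} syntax; \code{date} with
#' \code{ge}/\code{le}/\code{gt}/\code{lt} prefixes over effective, onset
#' and period dates (repeatable for ranges); reference search on
#' \code{subject} and \code{encounter}; and \code{_count} paging. Any other
#' parameter raises an \code{unsupported_search} error rather than being
#' silently ignored.
#'
#' @param store A \code{\link{fhir_store}}.
#' @param type Resource type to search.
#' @param params Named list of parameters; values may be vectors (date
#'   ranges).
#' @return List of matching resources (latest versions, undeleted).
#' @export
store_search <- function(store, type, params = list()) {
  unknown <- setdiff(names(params), SUPPORTED_SEARCH_PARAMS)
  if (length(unknown) > 0) {
    fc_stop("unsupported_search",
            sprintf("unsupported search parameter(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  res <- store_resources(store, type)
  keep <- vapply(res, function(r) {
    for (nm in names(params)) {
      vals <- as.character(params[[nm]])
      ok <- switch(nm,
        "_id" = identical(r$id, vals[[1]]),
        "_count" = TRUE,
        code = ,
        gender = ,
        identifier = any(vapply(vals, function(v) token_matches(r, nm, v), TRUE)),
        date = date_matches(r, vals),
        subject = ,
        encounter = any(vapply(vals, function(v) reference_matches(r, nm, v), TRUE))
      )
      if (!isTRUE(ok)) return(FALSE)
    }
    TRUE
  }, TRUE)
  out <- res[keep]
  if (!is.null(params$`_count`)) {
    out <- utils::head(out, as.integer(params$`_count`))
  }
  out
}

#' Generate the store's CapabilityStatement
#'
#' Lists every resource type with a loaded profile (plus any types already
#' stored), its supported profiles and the supported interactions. The
#' result round-trips through \code{\link{parse_capability_statement}}.
#'
#' @param store A \code{\link{fhir_store}}.
#' @return A CapabilityStatement JSON tree.
#' @export
capability_statement <- function(store) {
  types <- unique(c(
    vapply(store$profiles, `[[`, "", "resource_type"),
    vapply(ls(store$entries), function(k) strsplit(k, "/")[[1]][1], "")
  ))
  types <- sort(types[nzchar(types)])
  entries <- lapply(types, function(tp) {
    purls <- unname(vapply(
      Filter(function(p) identical(p$resource_type, tp), store$profiles),
      `[[`, "", "canonical_url"))
    e <- list(
      type = tp,
      interaction = lapply(c("create", "read", "update", "search-type"),
                           function(cd) list(code = cd))
    )
    if (length(purls) > 0) e$supportedProfile <- as.list(purls)
    e
  })
  list(
    resourceType = "CapabilityStatement",
    status = "active",
    date = fhir_now(),
    kind = "instance",
    implementation = list(url = store$base_url,
                          description = "fhircurate embedded repository"),
    fhirVersion = "4.0.1",
    format = list("json"),
    rest = list(list(
      mode = "server",
      security = list(
        cors = TRUE,
        description = "access control delegated to the hosting deployment; HTTP(S) with token-based authentication supported by contract"
      ),
      resource = entries
    ))
  )
}

#' Scan every stored resource for dangling references
#'
#' Walks all live resources, collects every \code{reference} string and
#' checks that it resolves to a live resource of the referenced type.
#'
#' @param store A \code{\link{fhir_store}}.
#' @return Data.frame of dangling references (\code{from}, \code{reference});
#'   zero rows when referential integrity holds.
#' @export
scan_references <- function(store) {
  collect_refs <- function(x) {
    if (!is.list(x)) return(character(0))
    refs <- character(0)
    if (!is.null(x$reference) && !is.list(x$reference)) {
      refs <- as.character(x$reference)
    }
    for (el in x) refs <- c(refs, collect_refs(el))
    refs
  }
  bad <- list()
  for (r in store_resources(store)) {
    for (ref in collect_refs(r)) {
      ok <- tryCatch({ resolve_url(store, ref); TRUE },
                     fhircurate_error = function(e) FALSE)
      if (!ok) {
        bad[[length(bad) + 1L]] <- data.frame(
          from = store_key(r$resourceType, r$id), reference = ref,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(bad) == 0) {
    return(data.frame(from = character(0), reference = character(0)))
  }
  do.call(rbind, bad)
}

#' Dump / load the store as NDJSON
#'
#' One resource per line, latest versions only. Round-trips through
#' \code{store_load_ndjson} into a fresh store.
#' @param store A \code{\link{fhir_store}}.
#' @param path NDJSON file path.
#' @return \code{store_dump_ndjson}: path invisibly; \code{store_load_ndjson}:
#'   the store invisibly.
#' @export
store_dump_ndjson <- function(store, path) {
  lines <- vapply(store_resources(store), function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname store_dump_ndjson
#' @export
store_load_ndjson <- function(store, path) {
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    store_put(store, jsonlite::fromJSON(line, simplifyVector = FALSE))
  }
  invisible(store)
}
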