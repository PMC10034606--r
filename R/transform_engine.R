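# Mapping execution: builds resource instances with deterministic hashed
# identifiers, applies terminology translations, gates on validation and
# emits session metadata (Provenance, DocumentManifest).

#' Deterministic resource id from a business key
#'
#' All resource ids and cross-references are generated with the same hashing
#' scheme, so a foreign-key column hashed as a reference lands on exactly
#' the id minted for the referenced row: SHA-256 over
#' \code{"<ResourceType>|<key>"}, lowercase hex (64 characters, which is
#' exactly the FHIR id length budget). Salting with the resource type keeps
#' ids distinct across types sharing a key.
#'
#' @param resource_type FHIR resource type.
#' @param business_key Nonempty key string (composite keys pre-joined with
#'   \code{"|"}).
#' @return A 64-character lowercase hex id, valid per the FHIR id pattern.
#' @examples
#' hash_id("Patient", "p001")
#' @export
hash_id <- function(resource_type, business_key) {
  key <- as.character(business_key)
  if (length(key) != 1 || is.na(key) || !nzchar(trimws(key))) {
    fc_stop("missing_id_key", "business key is empty or all-whitespace")
  }
  substr(digest::digest(paste0(resource_type, "|", key),
                        algo = "sha256", serialize = FALSE), 1, 64)
}

#' Coerce a translated code into the shape of its target element type
#' @noRd
coded_value <- function(system, code, type) {
  switch(type %||% "code",
    CodeableConcept = list(coding = list(list(system = system, code = code))),
    Coding = list(system = system, code = code),
    code)
}

#' Coerce a raw source cell into a typed FHIR literal
#' @noRd
typed_value <- function(cell, type, path) {
  cell <- trimws(as.character(cell))
  if (is.null(type) || is.na(type)) return(cell)
  if (type %in% c("decimal", "integer", "positiveInt", "unsignedInt")) {
    num <- parse_source_number(cell)
    if (is.na(num)) {
      fc_stop("unparseable_value",
              sprintf("value '%s' at %s is not numeric", cell, path))
    }
    return(if (type == "decimal") num else as.integer(num))
  }
  if (type %in% c("date", "dateTime", "instant")) {
    if (grepl("T", cell)) return(cell)  # already a datetime literal
    iso <- parse_source_date(cell)
    if (is.na(iso)) {
      fc_stop("unparseable_value",
              sprintf("value '%s' at %s is not a date", cell, path))
    }
    return(iso)
  }
  if (type == "CodeableConcept") return(list(coding = list(list(code = cell))))
  if (type == "Coding") return(list(code = cell))
  if (type == "Quantity") {
    num <- parse_source_number(cell)
    if (is.na(num)) {
      fc_stop("unparseable_value",
              sprintf("value '%s' at %s is not numeric", cell, path))
    }
    return(list(value = num))
  }
  if (type == "boolean") return(tolower(cell) %in% c("true", "1", "yes"))
  cell
}

#' Transform one source row into a FHIR resource instance
#'
#' Populates each mapped element path: \code{value} mappings become typed
#' literals (numbers parsed, dates normalized to ISO 8601, coded elements
#' translated before insertion), \code{reference} mappings become
#' \code{\{reference: "<Type>/<hash_id(Type, cell)>"\}} and \code{fixed}
#' mappings insert their literal. The resource id is
#' \code{hash_id(resource_type, id_columns joined with "|")}. Null cells
#' are skipped (validation decides whether that is acceptable).
#'
#' @param mapping A \code{\link{resource_mapping}} that passed
#'   \code{\link{check_mapping}} with zero errors.
#' @param row Named list (or one-row slice of a \code{source_table}) of
#'   cells keyed by column name.
#' @param profile The matching \code{fhir_profile} (drives type coercion).
#' @param index A \code{\link{index_concept_maps}} result.
#' @param remote_translate Optional remote \code{$translate} hook, see
#'   \code{\link{translate_code}}.
#' @return A FHIR resource JSON tree. Raises classed errors
#'   \code{missing_id_key}, \code{unparseable_value} or
#'   \code{untranslatable_code} for rejectable rows.
#' @export
transform_row <- function(mapping, row, profile, index = index_concept_maps(),
                          remote_translate = NULL) {
  cells <- as.list(row)
  keys <- unlist(cells[mapping$id_columns], use.names = FALSE)
  if (length(keys) != length(mapping$id_columns) ||
      any(vapply(keys, is_null_cell, TRUE))) {
    fc_stop("missing_id_key", sprintf(
      "required id column(s) %s missing or null",
      paste(mapping$id_columns, collapse = ",")))
  }
  rt <- mapping$resource_type
  resource <- list(resourceType = rt,
                   id = hash_id(rt, paste(trimws(keys), collapse = "|")))
  if (!is.null(mapping$profile_url)) {
    resource$meta <- list(profile = list(mapping$profile_url))
  }

  for (em in mapping$element_mappings) {
    parts <- strsplit(em$target_path, ".", fixed = TRUE)[[1]]
    if (parts[1] == rt) parts <- parts[-1]
    if (length(parts) == 0) next

    value <- NULL
    if (em$kind == "fixed") {
      value <- em$fixed_literal
    } else {
      cell <- cells[[em$source_column]]
      if (is_null_cell(cell)) next
      cell <- trimws(as.character(cell))
      if (em$kind == "reference") {
        value <- list(reference = paste0(em$reference_target, "/",
                                         hash_id(em$reference_target, cell)))
      } else {
        type <- resolve_element_type(profile, em$target_path)
        if (!is.null(em$translation)) {
          tr <- translate_code(cell, em$translation, index,
                               remote = remote_translate)
          value <- coded_value(tr$target_system, tr$target_code, type)
        } else {
          value <- typed_value(cell, type, em$target_path)
        }
      }
    }
    resource <- set_path(resource, parts, value)
  }
  resource
}

#' Does the resource carry nothing besides its identity?
#' @noRd
is_empty_resource <- function(resource) {
  length(setdiff(names(resource), c("resourceType", "id", "meta"))) == 0
}

new_record_error <- function(table, row_index, reason_code, detail) {
  data.frame(table = table, row_index = row_index, reason_code = reason_code,
             detail = detail, stringsAsFactors = FALSE)
}

reason_for_condition <- function(e) {
  cls <- class(e)
  if ("missing_id_key" %in% cls) "missing-id-key"
  else if ("unparseable_value" %in% cls) "unparseable-value"
  else if ("untranslatable_code" %in% cls) "untranslatable-code"
  else "validation-failed"
}

#' Build the session Provenance resource
#'
#' One Provenance per transformation session, targeting every resource the
#' session created, recorded at session end, attributed to the configured
#' author. Its id is a deterministic hash of the created-id set, so an
#' idempotent re-run updates (versions) the same Provenance rather than
#' duplicating it.
#'
#' @param session_id Session identifier.
#' @param created_ids Nonempty character vector of \code{"Type/id"} keys.
#' @param author Author display string.
#' @param recorded ISO timestamp of the session end.
#' @return A Provenance resource JSON tree.
#' @export
build_provenance <- function(session_id, created_ids, author, recorded = fhir_now()) {
  if (length(created_ids) == 0) {
    fc_stop("precondition", "no created resources; no Provenance to build")
  }
  list(
    resourceType = "Provenance",
    id = hash_id("Provenance", paste(sort(created_ids), collapse = "|")),
    target = lapply(created_ids, function(k) list(reference = k)),
    recorded = recorded,
    activity = list(coding = list(list(
      system = "http://terminology.hl7.org/CodeSystem/v3-DataOperation",
      code = "CREATE"))),
    agent = list(list(
      type = list(coding = list(list(
        system = "http://terminology.hl7.org/CodeSystem/provenance-participant-type",
        code = "assembler"))),
      who = list(display = author))),
    entity = list(list(role = "source",
                       what = list(display = paste("curation session", session_id))))
  )
}

#' Build the data-set DocumentManifest resource
#'
#' One DocumentManifest per data set, keeping the author and license
#' together with the other metadata: the author under
#' \code{author[0].display}, the license code verbatim in the free-text
#' \code{description} field (extension-free by design), and one
#' \code{content} reference per created resource.
#'
#' @param session_id Session identifier.
#' @param author Author display string.
#' @param license License code, e.g. \code{"CC-BY-4.0"}.
#' @param created_ids Nonempty character vector of \code{"Type/id"} keys.
#' @param created ISO timestamp.
#' @return A DocumentManifest resource JSON tree.
#' @export
build_manifest <- function(session_id, author, license, created_ids,
                           created = fhir_now()) {
  if (length(created_ids) == 0) {
    fc_stop("precondition", "no created resources; no DocumentManifest to build")
  }
  list(
    resourceType = "DocumentManifest",
    id = hash_id("DocumentManifest", paste(sort(created_ids), collapse = "|")),
    status = "current",
    created = created,
    source = paste0("urn:fhircurate:session:", session_id),
    author = list(list(display = author)),
    description = license,
    content = lapply(created_ids, function(k) list(reference = k))
  )
}

#' Execute a mapping configuration over source tables
#'
#' The full transformation session: every resource mapping is statically
#' checked, every source row is transformed and locally validated, invalid
#' resources are never written, and after the data resources are persisted
#' exactly one Provenance and one DocumentManifest are written. All writes
#' go through the store's create-or-update path, so persisted resources
#' carry version metadata and a re-run with identical inputs bumps versions
#' instead of duplicating. Resource generation and validation complete
#' before any write: a failing store leaves no partial session behind.
#'
#' Per table, \code{created + rejected == row_count}; every rejected row is
#' reported with one \code{RecordError} (reason codes
#' \code{missing-id-key}, \code{unparseable-value},
#' \code{untranslatable-code}, \code{validation-failed}).
#'
#' @param config A \code{\link{mapping_config}}.
#' @param sources Named list of \code{source_table}s (from
#'   \code{\link{open_source}}).
#' @param profiles Named list of \code{fhir_profile}s.
#' @param index A \code{\link{index_concept_maps}} result.
#' @param store A \code{\link{fhir_store}}.
#' @param author Session author recorded in the metadata resources.
#' @param license License code recorded on the DocumentManifest.
#' @param remote_validate Optional function \code{(resource) -> violations
#'   data.frame} implementing a remote \code{$validate}; when configured it
#'   is authoritative for persistence gating, after local validation.
#' @param remote_translate Optional remote \code{$translate} hook.
#' @return An object of class \code{transform_report}: list with
#'   \code{session_id}, \code{started}, \code{ended}, \code{created} (named
#'   counts per resource type), \code{created_ids}, \code{rejected} (a
#'   RecordError data.frame), \code{provenance_id}, \code{manifest_id}.
#' @export
run_session <- function(config, sources, profiles, index = index_concept_maps(),
                        store = fhir_store(profiles), author = "fhircurate",
                        license = "CC-BY-4.0", remote_validate = NULL,
                        remote_translate = NULL) {
  stopifnot(inherits(config, "mapping_config"), inherits(store, "fhir_store"))
  started <- fhir_now()

  # static gate: no session starts on a broken mapping
  for (rm in config$resource_mappings) {
    table <- sources[[rm$source_table]]
    if (is.null(table)) {
      fc_stop("precondition",
              sprintf("source table '%s' not provided", rm$source_table))
    }
    profile <- find_profile(profiles, rm$resource_type, rm$profile_url)
    issues <- check_mapping(rm, profile, table)
    if (any(issues$severity == "error")) {
      fc_stop("precondition", sprintf(
        "mapping for %s has %d blocking issue(s): %s", rm$source_table,
        sum(issues$severity == "error"),
        paste(utils::head(issues$message[issues$severity == "error"], 3),
              collapse = "; ")))
    }
  }

  pending <- list()
  rejected <- list()
  row_totals <- integer(0)

  for (rm in config$resource_mappings) {
    table <- sources[[rm$source_table]]
    profile <- find_profile(profiles, rm$resource_type, rm$profile_url)
    tname <- rm$source_table
    row_totals[tname] <- nrow(table)
    for (i in seq_len(nrow(table))) {
      row <- as.list(table[i, , drop = FALSE])
      res <- tryCatch(
        transform_row(rm, row, profile, index, remote_translate),
        fhircurate_error = function(e) e
      )
      if (inherits(res, "condition")) {
        rejected[[length(rejected) + 1L]] <- new_record_error(
          tname, i - 1L, reason_for_condition(res), conditionMessage(res))
        next
      }
      if (is_empty_resource(res)) {
        rejected[[length(rejected) + 1L]] <- new_record_error(
          tname, i - 1L, "validation-failed",
          "no populated element besides id; empty resources are not written")
        next
      }
      v <- validate_resource(res, profile, store$valuesets)
      if (!is.null(remote_validate)) {
        rv <- remote_validate(res)
        if (has_blocking_violation(rv)) v <- rbind(v, rv)
      }
      if (has_blocking_violation(v)) {
        rejected[[length(rejected) + 1L]] <- new_record_error(
          tname, i - 1L, "validation-failed",
          paste(v$detail[v$severity == "error"], collapse = "; "))
        next
      }
      pending[[length(pending) + 1L]] <- res
    }
  }

  # persistence phase: all-or-nothing with respect to session metadata
  created_ids <- character(0)
  created <- integer(0)
  for (res in pending) {
    store_put(store, res)
    key <- store_key(res$resourceType, res$id)
    if (!key %in% created_ids) {
      created_ids <- c(created_ids, key)
      prev <- created[res$resourceType]
      created[res$resourceType] <- if (is.na(prev)) 1L else prev + 1L
    }
  }

  ended <- fhir_now()
  # derived from the created-id set (not the clock) so that an idempotent
  # re-run updates the same session metadata instead of duplicating it
  session_id <- substr(digest::digest(created_ids, algo = "sha256"), 1, 16)
  provenance_id <- NA_character_
  manifest_id <- NA_character_
  if (length(created_ids) > 0) {
    prov <- build_provenance(session_id, created_ids, author, recorded = ended)
    man <- build_manifest(session_id, author, license, created_ids,
                          created = ended)
    store_put(store, prov)
    store_put(store, man)
    provenance_id <- prov$id
    manifest_id <- man$id
  }

  rejected_df <- if (length(rejected) == 0) {
    new_record_error(character(0), integer(0), character(0), character(0))
  } else {
    do.call(rbind, rejected)
  }

  structure(
    list(session_id = session_id, started = started, ended = ended,
         created = created, created_ids = created_ids,
         rejected = rejected_df, row_totals = row_totals,
         provenance_id = provenance_id, manifest_id = manifest_id,
         author = author, license = license),
    class = "transform_report"
  )
}

#' @export
print.transform_report <- function(x, ...) {
  cat("<transform_report> session", x$session_id, "\n")
  cat("  created: ",
      paste(sprintf("%s=%d", names(x$created), x$created), collapse = ", "),
      "\n", sep = "")
  cat("  rejected:", nrow(x$rejected), "row(s)\n")
  if (nrow(x$rejected) > 0) {
    tab <- table(x$rejected$reason_code)
    for (nm in names(tab)) cat(sprintf("    %-20s %d\n", nm, tab[[nm]]))
  }
  cat("  provenance:", x$provenance_id, "\n  manifest:  ", x$manifest_id, "\n")
  invisible(x)
}
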