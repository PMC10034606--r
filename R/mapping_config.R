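# The JSON mapping language: a versioned document tying source columns to
# profiled FHIR element paths. The schema is the package's own contract
# (see the shipped docs/ examples under extdata/mappings/).

MAPPING_KINDS <- c("value", "reference", "fixed")

#' Construct an element mapping
#'
#' One matching between a source column (or a fixed literal) and a profiled
#' FHIR element path.
#'
#' @param target_path Dotted element path, e.g. \code{"Observation.subject"}.
#' @param kind One of \code{"value"} (typed literal from a column),
#'   \code{"reference"} (hash-linked resource reference from a foreign-key
#'   column) or \code{"fixed"} (constant literal, used to satisfy
#'   profile-required elements absent from the source).
#' @param source_column Source column name (kinds value/reference).
#' @param reference_target Referenced resource type (kind reference).
#' @param fixed_literal Constant value (kind fixed); may be an atomic value
#'   or a named list for complex datatypes such as a Coding.
#' @param translation Optional \code{\link{translation_spec}}.
#' @return A list of class \code{element_mapping}.
#' @export
element_mapping <- function(target_path, kind = "value", source_column = NULL,
                            reference_target = NULL, fixed_literal = NULL,
                            translation = NULL) {
  kind <- match.arg(kind, MAPPING_KINDS)
  if (kind == "reference" && is.null(reference_target)) {
    fc_stop("mapping_invalid", sprintf(
      "reference mapping at %s needs a reference_target", target_path))
  }
  if (kind == "fixed" && (is.null(fixed_literal) || !is.null(source_column))) {
    fc_stop("mapping_invalid", sprintf(
      "fixed mapping at %s needs fixed_literal and no source_column", target_path))
  }
  if (kind == "value" && is.null(source_column)) {
    fc_stop("mapping_invalid", sprintf(
      "value mapping at %s needs a source_column", target_path))
  }
  structure(list(target_path = target_path, kind = kind,
                 source_column = source_column,
                 reference_target = reference_target,
                 fixed_literal = fixed_literal,
                 translation = translation),
            class = "element_mapping")
}

#' Construct a resource mapping
#'
#' Ties one source table to one FHIR resource type/profile. \code{id_columns}
#' form the business key hashed into the resource id (composite keys are
#' joined with "|" before hashing); one source row yields at most one
#' resource instance.
#'
#' @param source_table Source table name.
#' @param resource_type FHIR resource type.
#' @param id_columns Nonempty ordered character vector of key columns.
#' @param element_mappings List of \code{\link{element_mapping}}s.
#' @param profile_url Optional canonical profile URL.
#' @return A list of class \code{resource_mapping}.
#' @export
resource_mapping <- function(source_table, resource_type, id_columns,
                             element_mappings, profile_url = NULL) {
  if (length(id_columns) == 0) {
    fc_stop("mapping_invalid", "id_columns must be nonempty")
  }
  structure(list(source_table = source_table, resource_type = resource_type,
                 profile_url = profile_url,
                 id_columns = as.character(id_columns),
                 element_mappings = element_mappings),
            class = "resource_mapping")
}

#' Construct a mapping configuration
#'
#' The top-level mapping document: endpoints plus one
#' \code{\link{resource_mapping}} per source table.
#'
#' @param resource_mappings Nonempty list of resource mappings.
#' @param fhir_endpoint Target repository locator (\code{"embedded"} for the
#'   in-package store, or a base URL).
#' @param terminology_endpoint Optional terminology server base URL.
#' @param version Mapping-language version string.
#' @return A list of class \code{mapping_config}.
#' @export
mapping_config <- function(resource_mappings, fhir_endpoint = "embedded",
                           terminology_endpoint = NULL, version = "1.0") {
  if (length(resource_mappings) == 0) {
    fc_stop("mapping_invalid", "at least one resource mapping is required")
  }
  structure(list(version = version, fhir_endpoint = fhir_endpoint,
                 terminology_endpoint = terminology_endpoint,
                 resource_mappings = resource_mappings),
            class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat("<mapping_config> v", x$version, " -> ", x$fhir_endpoint, "\n", sep = "")
  for (rm in x$resource_mappings) {
    cat(sprintf("  %s -> %s (%d element mapping(s))\n", rm$source_table,
                rm$resource_type, length(rm$element_mappings)))
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

em_to_list <- function(em) {
  out <- list(target_path = em$target_path, kind = em$kind)
  if (!is.null(em$source_column)) out$source_column <- em$source_column
  if (!is.null(em$reference_target)) out$reference_target <- em$reference_target
  if (!is.null(em$fixed_literal)) out$fixed_literal <- em$fixed_literal
  if (!is.null(em$translation)) {
    out$translation <- Filter(Negate(is.null), unclass(em$translation))
  }
  out
}

#' Serialize / deserialize a mapping configuration
#'
#' \code{save_mapping} writes the stable JSON form of the document (or
#' returns it as a string when \code{path} is NULL); \code{load_mapping}
#' parses and structurally validates it, reporting the offending JSON
#' pointer on schema violations. \code{load_mapping(save_mapping(x))}
#' is the identity.
#'
#' @param config A \code{\link{mapping_config}}.
#' @param path Output file (save) or input file/JSON string (load).
#' @return \code{save_mapping}: the JSON string, invisibly when written to a
#'   file. \code{load_mapping}: a \code{mapping_config}.
#' @export
save_mapping <- function(config, path = NULL) {
  stopifnot(inherits(config, "mapping_config"))
  doc <- list(
    version = config$version,
    fhir_endpoint = config$fhir_endpoint,
    resource_mappings = lapply(config$resource_mappings, function(rm) {
      out <- list(source_table = rm$source_table,
                  resource_type = rm$resource_type,
                  id_columns = as.list(rm$id_columns),
                  element_mappings = lapply(rm$element_mappings, em_to_list))
      if (!is.null(rm$profile_url)) out$profile_url <- rm$profile_url
      out
    })
  )
  if (!is.null(config$terminology_endpoint)) {
    doc$terminology_endpoint <- config$terminology_endpoint
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

schema_fail <- function(pointer, what) {
  fc_stop("mapping_parse",
          sprintf("mapping document invalid at %s: %s", pointer, what))
}

need_string <- function(doc, key, pointer) {
  v <- doc[[key]]
  if (is.null(v) || !is.character(as.character(v)) || !nzchar(as.character(v))) {
    schema_fail(paste0(pointer, "/", key), "expected a nonempty string")
  }
  as.character(v)
}

#' @rdname save_mapping
#' @export
load_mapping <- function(path) {
  doc <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  version <- need_string(doc, "version", "")
  endpoint <- need_string(doc, "fhir_endpoint", "")
  rms <- doc$resource_mappings
  if (is.null(rms) || length(rms) == 0) {
    schema_fail("/resource_mappings", "expected a nonempty array")
  }
  parsed <- lapply(seq_along(rms), function(i) {
    ptr <- sprintf("/resource_mappings/%d", i - 1L)
    rm <- rms[[i]]
    st <- need_string(rm, "source_table", ptr)
    rt <- need_string(rm, "resource_type", ptr)
    idc <- rm$id_columns
    if (is.null(idc) || length(idc) == 0) {
      schema_fail(paste0(ptr, "/id_columns"), "expected a nonempty array")
    }
    ems <- lapply(seq_along(rm$element_mappings %||% list()), function(j) {
      eptr <- sprintf("%s/element_mappings/%d", ptr, j - 1L)
      em <- rm$element_mappings[[j]]
      tp <- need_string(em, "target_path", eptr)
      kind <- need_string(em, "kind", eptr)
      if (!kind %in% MAPPING_KINDS) {
        schema_fail(paste0(eptr, "/kind"),
                    paste("expected one of", paste(MAPPING_KINDS, collapse = "/")))
      }
      tr <- NULL
      if (!is.null(em$translation)) {
        tptr <- paste0(eptr, "/translation")
        tr <- translation_spec(
          source_system = need_string(em$translation, "source_system", tptr),
          target_system = need_string(em$translation, "target_system", tptr),
          concept_map_url = em$translation$concept_map_url
        )
      }
      tryCatch(
        element_mapping(tp, kind, source_column = em$source_column,
                        reference_target = em$reference_target,
                        fixed_literal = em$fixed_literal, translation = tr),
        fhircurate_error = function(e) schema_fail(eptr, conditionMessage(e))
      )
    })
    dup <- duplicated(vapply(ems, `[[`, "", "target_path"))
    if (any(dup)) {
      schema_fail(paste0(ptr, "/element_mappings"), "duplicate target paths")
    }
    resource_mapping(st, rt, vapply(idc, as.character, ""), ems,
                     profile_url = rm$profile_url)
  })
  mapping_config(parsed, fhir_endpoint = endpoint,
                 terminology_endpoint = doc$terminology_endpoint,
                 version = version)
}

# ---- static checking -------------------------------------------------------

#' Leaf datatypes of common FHIR complex types
#'
#' Shallow element tables for the complex datatypes the engine can descend
#' into when a mapping targets a sub-element (e.g. Observation.valueQuantity.value).
#' @noRd
FHIR_DATATYPES <- list(
  Quantity = list(value = "decimal", unit = "string", system = "uri",
                  code = "code", comparator = "code"),
  Coding = list(system = "uri", code = "code", display = "string",
                version = "string"),
  CodeableConcept = list(coding = "Coding", text = "string"),
  Period = list(start = "dateTime", end = "dateTime"),
  Reference = list(reference = "string", display = "string", type = "uri"),
  Identifier = list(system = "uri", value = "string", use = "code"),
  HumanName = list(family = "string", given = "string", text = "string",
                   use = "code"),
  Annotation = list(text = "string", time = "dateTime")
)

PRIMITIVE_TYPES <- c("string", "code", "uri", "url", "canonical", "id",
                     "boolean", "integer", "decimal", "date", "dateTime",
                     "instant", "time", "markdown", "positiveInt", "unsignedInt")

#' Resolve the primitive datatype at a dotted path under a profile
#'
#' Finds the longest constraint path that prefixes \code{path} and walks the
#' remaining segments through the complex-datatype tables. Returns the
#' primitive type code, a complex type code if the path stops there, or NA
#' when the path cannot be resolved.
#' @noRd
resolve_element_type <- function(profile, path) {
  cs <- profile$constraints
  hits <- cs$path[cs$path == path | startsWith(path, paste0(cs$path, "."))]
  if (length(hits) == 0) return(NA_character_)
  anchor <- hits[which.max(nchar(hits))]
  i <- match(anchor, cs$path)
  types <- cs$types[[i]]
  if (anchor == path) {
    return(if (length(types) >= 1) types[[1]] else NA_character_)
  }
  rest <- strsplit(substring(path, nchar(anchor) + 2), ".", fixed = TRUE)[[1]]
  cur <- if (length(types) >= 1) types[[1]] else NA_character_
  for (seg in rest) {
    if (is.na(cur)) return(NA_character_)
    tab <- FHIR_DATATYPES[[cur]]
    if (is.null(tab) || is.null(tab[[seg]])) return(NA_character_)
    cur <- tab[[seg]]
  }
  cur
}

#' Binding constraint in force at a path (the path itself or an ancestor)
#' @noRd
binding_at <- function(profile, path) {
  cs <- profile$constraints
  cand <- which(cs$path == path |
                  startsWith(path, paste0(cs$path, ".")))
  cand <- cand[!is.na(cs$binding_strength[cand]) &
                 nzchar(cs$binding_strength[cand])]
  if (length(cand) == 0) return(NULL)
  i <- cand[which.max(nchar(cs$path[cand]))]
  list(strength = cs$binding_strength[i], valueset = cs$binding_valueset[i])
}

new_issue <- function(severity, code, target_path, message) {
  data.frame(severity = severity, code = code, target_path = target_path,
             message = message, stringsAsFactors = FALSE)
}

#' Statically check a resource mapping against a profile and a source table
#'
#' Reports, before any row is transformed:
#' \itemize{
#'   \item \code{missing-required} (error): a profile element with min >= 1
#'     that no element mapping populates (directly or via a sub-path);
#'   \item \code{unknown-path} (error): a target path absent from the
#'     profile's constraint model;
#'   \item \code{unknown-column} (error): a source column (or id column)
#'     absent from the table;
#'   \item \code{duplicate-target} (error): two mappings to the same path;
#'   \item \code{type-incompatible} (warning): a text column mapped into a
#'     numeric or date element;
#'   \item \code{binding-untranslated} (warning): a required-binding coded
#'     element mapped from a source column with no terminology translation.
#' }
#'
#' Adding an element mapping never introduces a \code{missing-required}
#' error for another path (the check is monotone).
#'
#' @param mapping A \code{\link{resource_mapping}}.
#' @param profile The matching \code{fhir_profile}.
#' @param table The \code{source_table} named by the mapping.
#' @return A data.frame of issues (possibly zero rows) with columns
#'   \code{severity}, \code{code}, \code{target_path}, \code{message}.
#' @export
check_mapping <- function(mapping, profile, table) {
  stopifnot(inherits(mapping, "resource_mapping"),
            inherits(profile, "fhir_profile"),
            inherits(table, "source_table"))
  if (!identical(mapping$resource_type, profile$resource_type)) {
    fc_stop("precondition",
            sprintf("mapping targets %s but profile defines %s",
                    mapping$resource_type, profile$resource_type))
  }
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- new_issue(...)
  cols <- names(table)
  targets <- vapply(mapping$element_mappings, `[[`, "", "target_path")

  dup <- unique(targets[duplicated(targets)])
  for (p in dup) add("error", "duplicate-target", p, "multiple mappings to the same path")

  for (req in required_paths(profile)) {
    covered <- any(targets == req | startsWith(targets, paste0(req, ".")) |
                     startsWith(req, paste0(targets, ".")))
    if (!covered) {
      add("error", "missing-required", req,
          sprintf("profile requires %s (min >= 1) but no mapping populates it", req))
    }
  }

  for (em in mapping$element_mappings) {
    p <- em$target_path
    # a path is known when it is a profile constraint, or a sub-element
    # reachable from one through a complex datatype (never a bare child of
    # the resource root)
    known <- p %in% profile$constraints$path ||
      !is.na(resolve_element_type(profile, p))
    if (!known) {
      add("error", "unknown-path", p,
          sprintf("%s is not an element of profile %s", p, profile$canonical_url))
      next
    }
    if (!is.null(em$source_column) && !(em$source_column %in% cols)) {
      add("error", "unknown-column", p,
          sprintf("source column '%s' not found in table '%s'",
                  em$source_column, source_table_name(table)))
      next
    }
    if (em$kind == "value" && !is.null(em$source_column)) {
      leaf <- resolve_element_type(profile, p)
      decl <- source_column_types(table)[[em$source_column]] %||% "unknown"
      if (!is.na(leaf)) {
        num_leaf <- leaf %in% c("decimal", "integer", "positiveInt", "unsignedInt", "Quantity")
        date_leaf <- leaf %in% c("date", "dateTime", "instant")
        if (num_leaf && decl == "text") {
          add("warning", "type-incompatible", p, sprintf(
            "text column '%s' mapped into %s element", em$source_column, leaf))
        } else if (date_leaf && !decl %in% c("date", "datetime", "unknown")) {
          add("warning", "type-incompatible", p, sprintf(
            "column '%s' (declared %s) mapped into %s element",
            em$source_column, decl, leaf))
        }
      }
      b <- binding_at(profile, p)
      if (!is.null(b) && identical(b$strength, "required") && is.null(em$translation)) {
        add("warning", "binding-untranslated", p, sprintf(
          "%s has a required binding to %s but no terminology translation is configured",
          p, b$valueset))
      }
    }
  }

  for (idc in mapping$id_columns) {
    if (!(idc %in% cols)) {
      add("error", "unknown-column", paste0(mapping$resource_type, ".id"),
          sprintf("id column '%s' not found in table '%s'",
                  idc, source_table_name(table)))
    }
  }

  if (length(issues) == 0) {
    return(new_issue(character(0), character(0), character(0), character(0)))
  }
  do.call(rbind, issues)
}
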