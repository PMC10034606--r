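# RDA FAIR Data Maturity Model scoring: a data-driven indicator catalogue
# (editable JSON, shipped under extdata/fair/) whose indicators are probed
# against concrete repository facts, then rolled up into per-principle
# maturity levels 0-5.

#' Load the FAIR maturity indicator catalogue
#'
#' The shipped catalogue follows the public RDA FAIR Data Maturity Model:
#' 41 indicators partitioned over the F/A/I/R principles, each with an RDA
#' identifier, a priority (essential / important / useful) and the name of
#' the probe that checks it against a repository. Editing the JSON changes
#' the assessment without a code change.
#'
#' @param path Catalogue JSON file; defaults to the shipped RDA catalogue.
#' @return Data.frame with columns \code{indicator_id}, \code{principle},
#'   \code{priority}, \code{probe}, \code{description}.
#' @export
load_fair_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- fhircurate_extdata("fair", "rda_indicators.json")
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  df <- do.call(rbind, lapply(doc, function(ind) {
    data.frame(indicator_id = ind$id, principle = ind$principle,
               priority = ind$priority, probe = ind$probe,
               description = ind$description %||% "",
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$indicator_id)) {
    fc_stop("malformed_catalogue", "duplicate indicator ids in catalogue")
  }
  if (!all(df$principle %in% c("F", "A", "I", "R")) ||
      !all(df$priority %in% c("essential", "important", "useful"))) {
    fc_stop("malformed_catalogue", "bad principle or priority in catalogue")
  }
  df
}

# ---- probes ----------------------------------------------------------------
# Each probe tests a literal fact of the repository or session report, never
# a downstream claim. Probes quantifying over resources fail on an empty
# store: an empty repository satisfies nothing.

METADATA_TYPES <- c("Provenance", "DocumentManifest")

store_data_resources <- function(store) {
  Filter(function(r) !r$resourceType %in% METADATA_TYPES,
         store_resources(store))
}

store_metadata_resources <- function(store) {
  Filter(function(r) r$resourceType %in% METADATA_TYPES,
         store_resources(store))
}

all_resolve <- function(store, resources) {
  length(resources) > 0 && all(vapply(resources, function(r) {
    tryCatch({
      resolve_url(store, resource_url(store, r$resourceType, r$id))
      TRUE
    }, fhircurate_error = function(e) FALSE)
  }, TRUE))
}

collect_codings <- function(x) {
  if (!is.list(x)) return(list())
  out <- list()
  if (!is.null(x$code) && !is.list(x$code) && "system" %in% names(x)) {
    out[[1]] <- list(system = x$system, code = x$code)
  }
  for (el in x) out <- c(out, collect_codings(el))
  out
}

KNOWN_LICENSES <- c("CC0-1.0", "CC-BY-4.0", "CC-BY-SA-4.0", "CC-BY-NC-4.0",
                    "ODC-By-1.0", "ODbL-1.0")

fair_probes <- function() list(
  # F: identifiers, rich searchable metadata
  metadata_identifiers_resolve = function(store, report) {
    all_resolve(store, store_metadata_resources(store))
  },
  data_identifiers_resolve = function(store, report) {
    all_resolve(store, store_data_resources(store))
  },
  identifiers_unique_persistent = function(store, report) {
    res <- store_resources(store)
    ids <- vapply(res, function(r) store_key(r$resourceType, r$id), "")
    length(ids) > 0 && !anyDuplicated(ids) &&
      all(grepl(FHIR_ID_REGEX, vapply(res, `[[`, "", "id")))
  },
  rich_metadata = function(store, report) {
    length(store_resources(store, "Provenance")) > 0 &&
      length(store_resources(store, "DocumentManifest")) > 0
  },
  metadata_lists_data_ids = function(store, report) {
    provs <- store_resources(store, "Provenance")
    length(provs) > 0 && all(vapply(provs, function(p) {
      targets <- vapply(p$target, function(t) as.character(t$reference), "")
      length(targets) > 0 && all(vapply(targets, function(ref) {
        tryCatch({ resolve_url(store, ref); TRUE },
                 fhircurate_error = function(e) FALSE)
      }, TRUE))
    }, TRUE))
  },
  metadata_searchable = function(store, report) {
    provs <- store_resources(store, "Provenance")
    length(provs) > 0 &&
      length(store_search(store, "Provenance",
                          list(`_id` = provs[[1]]$id))) == 1
  },
  # A: protocol contract, retrievability, metadata persistence
  access_info_in_metadata = function(store, report) {
    caps <- capability_statement(store)
    !is.null(caps$implementation$url) && length(store_resources(store)) > 0
  },
  standard_protocol = function(store, report) {
    caps <- capability_statement(store)
    length(store_resources(store)) > 0 &&
      identical(caps$resourceType, "CapabilityStatement") &&
      length(caps$rest) > 0 && identical(caps$rest[[1]]$mode, "server")
  },
  auth_supported = function(store, report) {
    caps <- capability_statement(store)
    length(store_resources(store)) > 0 && !is.null(caps$rest[[1]]$security)
  },
  open_free_protocol = function(store, report) {
    caps <- capability_statement(store)
    length(store_resources(store)) > 0 &&
      "json" %in% unlist(caps$format) && !is.null(caps$fhirVersion)
  },
  data_retrievable = function(store, report) {
    res <- store_data_resources(store)
    length(res) > 0 && all(vapply(res, function(r) {
      tryCatch({ store_get(store, r$resourceType, r$id); TRUE },
               fhircurate_error = function(e) FALSE)
    }, TRUE))
  },
  metadata_persistence = function(store, report) {
    isTRUE(store$soft_delete) &&
      length(store_metadata_resources(store)) > 0
  },
  # I: standard representation, vocabularies, qualified references
  standard_representation = function(store, report) {
    res <- store_resources(store)
    length(res) > 0 && all(vapply(res, function(r) {
      !is.null(r$resourceType) &&
        nzchar(as.character(jsonlite::toJSON(r, auto_unbox = TRUE)))
    }, TRUE))
  },
  machine_readable_model = function(store, report) {
    length(store$profiles) > 0 && length(store_resources(store)) > 0
  },
  standard_vocabularies = function(store, report) {
    res <- store_data_resources(store)
    if (length(res) == 0) return(FALSE)
    codings <- unlist(lapply(res, collect_codings), recursive = FALSE)
    length(codings) > 0 && all(vapply(codings, function(cd) {
      !is.null(cd$system) && grepl("^(https?://|urn:)", as.character(cd$system))
    }, TRUE))
  },
  qualified_references = function(store, report) {
    length(store_resources(store)) > 0 && nrow(scan_references(store)) == 0
  },
  # R: attributes, license, provenance, community compliance
  provenance_attributes = function(store, report) {
    provs <- store_resources(store, "Provenance")
    length(provs) > 0 && all(vapply(provs, function(p) {
      !is.null(p$recorded) && length(p$agent) > 0 && length(p$target) > 0
    }, TRUE))
  },
  license_present = function(store, report) {
    mans <- store_resources(store, "DocumentManifest")
    length(mans) > 0 && all(vapply(mans, function(m) {
      !is.null(m$description) && nzchar(m$description) &&
        length(m$author) > 0
    }, TRUE))
  },
  standard_license = function(store, report) {
    mans <- store_resources(store, "DocumentManifest")
    length(mans) > 0 && all(vapply(mans, function(m) {
      (m$description %||% "") %in% KNOWN_LICENSES
    }, TRUE))
  },
  provenance_standard = function(store, report) {
    provs <- store_resources(store, "Provenance")
    length(provs) > 0 && all(vapply(provs, function(p) {
      identical(p$resourceType, "Provenance") && length(p$target) > 0
    }, TRUE))
  },
  revalidation_passes = function(store, report) {
    res <- store_data_resources(store)
    length(res) > 0 && all(vapply(res, function(r) {
      !has_blocking_violation(store_validate(store, r))
    }, TRUE))
  }
)

#' Per-principle maturity level from indicator outcomes
#'
#' The roll-up rule: 5 when every indicator of the principle passes; 4 when
#' all essential and important indicators pass and some but not all useful
#' ones pass; 3 when all essential and important pass and no useful one
#' passes; 2 when all essential pass; 1 when at least one essential passes;
#' 0 otherwise. A principle with no passing indicator at all is level 0
#' regardless (so an empty repository scores 0 even for principles whose
#' catalogue has no essential indicator).
#'
#' @param principle One of "F", "A", "I", "R".
#' @param per_indicator Data.frame with columns \code{principle},
#'   \code{priority}, \code{status} (\code{pass}/\code{fail}/
#'   \code{not_considered}) covering all catalogue indicators of the
#'   principle.
#' @return Integer level 0-5.
#' @export
fair_level <- function(principle, per_indicator) {
  ind <- per_indicator[per_indicator$principle == principle, , drop = FALSE]
  if (nrow(ind) == 0) return(0L)
  pass <- ind$status == "pass"
  if (!any(pass)) return(0L)
  ess <- ind$priority == "essential"
  imp <- ind$priority == "important"
  use <- ind$priority == "useful"
  if (all(pass)) return(5L)
  if (all(pass[ess | imp])) {
    if (any(pass[use]) && !all(pass[use])) return(4L)
    if (!any(pass[use])) return(3L)
  }
  if (all(pass[ess])) return(2L)
  if (any(pass[ess])) return(1L)
  0L
}

#' Assess FAIR maturity of a curated repository
#'
#' Runs every catalogue indicator's probe against the store and the
#' transformation report and rolls outcomes up into per-principle levels.
#' The cross-community provenance-language indicator is scored
#' \code{not_considered}: the repository deliberately uses the health-care
#' community standard (HL7 FHIR) rather than a cross-community provenance
#' language, and \code{not_considered} is how the maturity model records a
#' deliberate non-goal. Deterministic given a fixed store state.
#'
#' @param store A \code{\link{fhir_store}} populated by a completed session
#'   (Provenance and DocumentManifest present; if absent the R-principle
#'   probes fail rather than error).
#' @param report The session's \code{transform_report} (or NULL).
#' @param catalogue Indicator catalogue from \code{\link{load_fair_catalogue}}.
#' @return An object of class \code{fair_assessment}: list with
#'   \code{per_indicator} (data.frame of indicator_id, principle, priority,
#'   status), \code{per_principle_level} (named integer vector for F/A/I/R)
#'   and \code{unmet_count} (failed + not_considered indicators).
#' @export
assess_fair <- function(store, report = NULL,
                        catalogue = load_fair_catalogue()) {
  probes <- fair_probes()
  status <- vapply(seq_len(nrow(catalogue)), function(i) {
    probe <- catalogue$probe[i]
    if (probe == "not_considered") return("not_considered")
    fn <- probes[[probe]]
    if (is.null(fn)) {
      fc_stop("malformed_catalogue",
              sprintf("indicator %s names unknown probe '%s'",
                      catalogue$indicator_id[i], probe))
    }
    if (isTRUE(tryCatch(fn(store, report),
                        fhircurate_error = function(e) FALSE))) "pass" else "fail"
  }, "")
  per_indicator <- data.frame(
    indicator_id = catalogue$indicator_id,
    principle = catalogue$principle,
    priority = catalogue$priority,
    status = status,
    stringsAsFactors = FALSE
  )
  levels <- vapply(c(F = "F", A = "A", I = "I", R = "R"),
                   fair_level, 0L, per_indicator = per_indicator)
  structure(
    list(per_indicator = per_indicator,
         per_principle_level = levels,
         unmet_count = sum(status != "pass")),
    class = "fair_assessment"
  )
}

#' @export
print.fair_assessment <- function(x, ...) {
  cat("<fair_assessment>\n")
  for (p in c("F", "A", "I", "R")) {
    ind <- x$per_indicator[x$per_indicator$principle == p, ]
    cat(sprintf("  %s: level %d  (%d/%d indicators pass)\n", p,
                x$per_principle_level[[p]], sum(ind$status == "pass"),
                nrow(ind)))
  }
  unmet <- x$per_indicator[x$per_indicator$status != "pass", ]
  if (nrow(unmet) > 0) {
    cat("  unmet:\n")
    for (i in seq_len(nrow(unmet))) {
      cat(sprintf("    %s (%s, %s): %s\n", unmet$indicator_id[i],
                  unmet$principle[i], unmet$priority[i], unmet$status[i]))
    }
  }
  invisible(x)
}
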