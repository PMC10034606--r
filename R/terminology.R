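# Terminology translation with ConceptMap semantics. Offline mode indexes
# local ConceptMap JSON files; a remote $translate hook can be plugged in
# when a terminology endpoint is configured.

#' Construct a translation specification
#'
#' Declares the code-system pair of a coded element mapping. When source and
#' target systems are identical the translation is an identity passthrough
#' (e.g. a source already coded in ICD-10 written into an ICD-10-bound
#' element needs no ConceptMap).
#'
#' @param source_system Source code system URI.
#' @param target_system Target code system URI enforced by the profile.
#' @param concept_map_url Optional canonical URL restricting lookup to one
#'   ConceptMap.
#' @return A list of class \code{translation_spec}.
#' @export
translation_spec <- function(source_system, target_system,
                             concept_map_url = NULL) {
  structure(list(source_system = source_system,
                 target_system = target_system,
                 concept_map_url = concept_map_url),
            class = "translation_spec")
}

#' Index ConceptMap resources for deterministic code lookup
#'
#' Flattens the \code{group/element/target} structure of FHIR R4 ConceptMaps
#' into a (source system, source code) -> (target system, target code) map.
#' Targets with equivalence \code{"unmatched"} or \code{"disjoint"} are
#' skipped. Translations are one-to-one: a source key mapped to two
#' different targets (within or across maps) is an ambiguity error.
#'
#' @param maps List of parsed ConceptMap JSON trees (or a directory path
#'   containing \code{.json} ConceptMap files).
#' @return An object of class \code{concept_map_index}.
#' @export
index_concept_maps <- function(maps = list()) {
  if (is.character(maps) && length(maps) == 1 && dir.exists(maps)) {
    files <- list.files(maps, pattern = "\\.json$", full.names = TRUE)
    docs <- lapply(files, read_fhir_json)
    maps <- Filter(function(d) identical(d$resourceType, "ConceptMap"), docs)
  }
  idx <- new.env(parent = emptyenv())
  for (cm in maps) {
    if (!identical(cm$resourceType, "ConceptMap")) {
      fc_stop("malformed_conformance", "document is not a ConceptMap")
    }
    for (g in cm$group %||% list()) {
      src_sys <- g$source
      tgt_sys <- g$target
      for (el in g$element %||% list()) {
        for (tg in el$target %||% list()) {
          eq <- tg$equivalence %||% "equivalent"
          if (eq %in% c("unmatched", "disjoint")) next
          key <- paste0(src_sys, "|", el$code)
          entry <- list(target_system = tgt_sys, target_code = tg$code,
                        equivalence = eq,
                        concept_map_url = cm$url %||% NA_character_)
          prev <- idx[[key]]
          if (!is.null(prev) &&
              !(identical(prev$target_system, entry$target_system) &&
                  identical(prev$target_code, entry$target_code))) {
            fc_stop("ambiguous_translation", sprintf(
              "conflicting translations for %s: %s|%s vs %s|%s",
              key, prev$target_system, prev$target_code,
              entry$target_system, entry$target_code))
          }
          idx[[key]] <- entry
        }
      }
    }
  }
  structure(list(entries = idx), class = "concept_map_index")
}

#' Number of indexed translations
#' @param index A \code{concept_map_index}.
#' @return Integer count of (system, code) keys.
#' @export
concept_map_size <- function(index) {
  stopifnot(inherits(index, "concept_map_index"))
  length(ls(index$entries))
}

#' @export
print.concept_map_index <- function(x, ...) {
  cat("<concept_map_index>", concept_map_size(x), "translation(s)\n")
  invisible(x)
}

#' Translate a code between code systems
#'
#' Pure function of \code{(code, spec, index)}: identity passthrough when
#' the spec's systems coincide, local ConceptMap lookup otherwise, with an
#' optional remote \code{$translate} fallback hook. A code with no
#' translation raises an \code{untranslatable_code} error carrying the
#' offending code (the source row becomes a rejected record downstream).
#'
#' @param code Nonempty code string.
#' @param spec A \code{\link{translation_spec}}.
#' @param index A \code{\link{index_concept_maps}} result.
#' @param remote Optional function \code{(code, spec) -> list(target_system,
#'   target_code)} implementing the FHIR \code{ConceptMap/$translate}
#'   request against a terminology endpoint; NULL means offline mode.
#' @return \code{list(target_system, target_code)}.
#' @export
translate_code <- function(code, spec, index = index_concept_maps(),
                           remote = NULL) {
  stopifnot(inherits(spec, "translation_spec"))
  code <- trimws(as.character(code))
  if (!nzchar(code)) fc_stop("untranslatable_code", "empty code")
  if (identical(spec$source_system, spec$target_system)) {
    return(list(target_system = spec$target_system, target_code = code))
  }
  entry <- index$entries[[paste0(spec$source_system, "|", code)]]
  if (!is.null(entry)) {
    if (!is.null(spec$concept_map_url) &&
        !identical(entry$concept_map_url, spec$concept_map_url)) {
      entry <- NULL
    } else if (!identical(entry$target_system, spec$target_system)) {
      entry <- NULL
    }
  }
  if (!is.null(entry)) {
    return(list(target_system = entry$target_system,
                target_code = entry$target_code))
  }
  if (!is.null(remote)) {
    res <- remote(code, spec)
    if (!is.null(res)) return(res)
  }
  fc_stop("untranslatable_code",
          sprintf("no translation for code '%s' from %s to %s",
                  code, spec$source_system, spec$target_system),
          code = code)
}
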