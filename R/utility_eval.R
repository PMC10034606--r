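# Privacy-concerned data-utility criteria, computed twice: directly on the
# source tables and via search queries against the FHIR store. Agreement of
# the two sides (accuracy %) measures whether the transformation preserved
# analytical content without exposing value distributions.

UTILITY_CRITERIA <- SYNTH_CRITERIA

norm_code <- function(x) toupper(trimws(as.character(x)))

read_dates <- function(x, fmt) {
  if (fmt == "%Y-%m-%d") as.Date(x) else as.Date(x, format = fmt)
}

#' Top-n condition codes by frequency, ties broken lexicographically
#' @noRd
top_condition_codes <- function(codes, n = 5L) {
  tab <- table(norm_code(codes))
  ord <- order(-as.integer(tab), names(tab))
  utils::head(names(tab)[ord], n)
}

# ---- source side -----------------------------------------------------------

src <- function(tables, schema, role) {
  t <- tables[[schema$tables[[role]]]]
  if (is.null(t)) fc_stop("precondition", sprintf("table for role '%s' missing", role))
  t
}

col <- function(table, schema, role) table[[schema$columns[[role]]]]

source_patients_by_gender <- function(tables, schema, gender) {
  p <- src(tables, schema, "patients")
  local <- col(p, schema, "gender")
  admin <- unname(schema$gender_codes[as.character(local)])
  col(p, schema, "patient_id")[!is.na(admin) & admin == gender]
}

#' Compute one utility criterion on the source tables
#'
#' @param criterion One of \code{female_top5}, \code{copd},
#'   \code{polypharmacy5}, \code{readmit30}, \code{hgb_male_range}.
#' @param tables Named list of \code{source_table}s.
#' @param schema An \code{\link{institution_schema}} describing table and
#'   column roles and the local gender code map.
#' @return Integer count.
#' @export
utility_source <- function(criterion, tables, schema = institution_schema("A")) {
  criterion <- match.arg(criterion, UTILITY_CRITERIA)
  switch(criterion,
    female_top5 = {
      cd <- src(tables, schema, "conditions")
      if (nrow(cd) == 0) return(0L)
      top5 <- top_condition_codes(col(cd, schema, "condition_code"))
      hit <- col(cd, schema, "patient_id")[
        norm_code(col(cd, schema, "condition_code")) %in% top5]
      length(intersect(unique(hit),
                       source_patients_by_gender(tables, schema, "female")))
    },
    copd = {
      cd <- src(tables, schema, "conditions")
      hit <- col(cd, schema, "patient_id")[
        norm_code(col(cd, schema, "condition_code")) %in% COPD_CODES]
      length(unique(hit))
    },
    polypharmacy5 = {
      rx <- src(tables, schema, "prescriptions")
      if (nrow(rx) == 0) return(0L)
      meds <- tapply(norm_code(col(rx, schema, "med_code")),
                     col(rx, schema, "patient_id"),
                     function(x) length(unique(x)))
      sum(meds >= 5)
    },
    readmit30 = {
      ad <- src(tables, schema, "admissions")
      count_readmissions(
        data.frame(patient = col(ad, schema, "patient_id"),
                   start = read_dates(col(ad, schema, "admit_date"),
                                      schema$date_format),
                   end = read_dates(col(ad, schema, "discharge_date"),
                                    schema$date_format)))
    },
    hgb_male_range = {
      ob <- src(tables, schema, "observations")
      v <- suppressWarnings(as.numeric(col(ob, schema, "obs_value")))
      hit <- col(ob, schema, "patient_id")[
        norm_code(col(ob, schema, "obs_code")) == "718-7" &
          !is.na(v) & v >= 138 & v <= 172]
      length(intersect(unique(hit),
                       source_patients_by_gender(tables, schema, "male")))
    }
  )
}

#' Count admissions starting within 30 days of the previous discharge
#'
#' An admission qualifies when its start date is at most 30 days
#' (inclusive) after the discharge date of the same patient's most recent
#' prior admission (by start date).
#' @noRd
count_readmissions <- function(stays, window = 30L) {
  stays <- stays[!is.na(stays$start), , drop = FALSE]
  n <- 0L
  for (p in unique(stays$patient)) {
    s <- stays[stays$patient == p, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2) next
    for (i in 2:nrow(s)) {
      prior_end <- max(s$end[seq_len(i - 1)], na.rm = TRUE)
      gap <- as.integer(s$start[i] - prior_end)
      if (!is.na(gap) && gap >= 0 && gap <= window) n <- n + 1L
    }
  }
  n
}

# ---- store side ------------------------------------------------------------

subject_id <- function(resource) {
  ref <- resource$subject$reference
  if (is.null(ref)) NA_character_ else sub("^.*/", "", ref)
}

store_patients_by_gender <- function(store, gender) {
  vapply(store_search(store, "Patient", list(gender = gender)),
         `[[`, "", "id")
}

condition_code_of <- function(r) {
  cp <- coding_pairs(r$code)
  if (length(cp) == 0) NA_character_ else norm_code(cp[[1]]$code)
}

#' Compute one utility criterion via FHIR store queries
#'
#' Mirrors \code{\link{utility_source}} on the transformed side: cohorts
#' are derived from Patient/Condition/MedicationStatement/Encounter/
#' Observation resources through the store's search interface.
#'
#' @param criterion Criterion id, see \code{\link{utility_source}}.
#' @param store A populated \code{\link{fhir_store}}.
#' @return Integer count.
#' @export
utility_store <- function(criterion, store) {
  criterion <- match.arg(criterion, UTILITY_CRITERIA)
  switch(criterion,
    female_top5 = {
      conds <- store_search(store, "Condition")
      if (length(conds) == 0) return(0L)
      codes <- vapply(conds, condition_code_of, "")
      top5 <- top_condition_codes(codes)
      hit <- unique(vapply(conds[codes %in% top5], subject_id, ""))
      length(intersect(hit, store_patients_by_gender(store, "female")))
    },
    copd = {
      hits <- unlist(lapply(COPD_CODES, function(code) {
        vapply(store_search(store, "Condition", list(code = code)),
               subject_id, "")
      }))
      length(unique(hits))
    },
    polypharmacy5 = {
      ms <- store_search(store, "MedicationStatement")
      if (length(ms) == 0) return(0L)
      subj <- vapply(ms, subject_id, "")
      code <- vapply(ms, function(r) {
        cp <- coding_pairs(r$medicationCodeableConcept)
        if (length(cp) == 0) NA_character_ else norm_code(cp[[1]]$code)
      }, "")
      meds <- tapply(code, subj, function(x) length(unique(x)))
      sum(meds >= 5)
    },
    readmit30 = {
      enc <- store_search(store, "Encounter")
      if (length(enc) == 0) return(0L)
      count_readmissions(data.frame(
        patient = vapply(enc, subject_id, ""),
        start = as.Date(vapply(enc, function(r)
          substr(r$period$start %||% NA_character_, 1, 10), "")),
        end = as.Date(vapply(enc, function(r)
          substr(r$period$end %||% NA_character_, 1, 10), ""))))
    },
    hgb_male_range = {
      hgb <- store_search(store, "Observation", list(code = "718-7"))
      v <- vapply(hgb, function(r) {
        val <- r$valueQuantity$value
        if (is.null(val)) NA_real_ else as.numeric(val)
      }, 0)
      hit <- unique(vapply(hgb[!is.na(v) & v >= 138 & v <= 172], subject_id, ""))
      length(intersect(hit, store_patients_by_gender(store, "male")))
    }
  )
}

#' Evaluate all data-utility criteria on both sides
#'
#' Computes the five privacy-concerned criteria on the source tables
#' (direct computation) and on the FHIR store (search queries) and reports
#' per-criterion accuracy
#' \code{100 * (1 - |source - transformed| / max(source, 1))} (100 when
#' both sides are 0). On a corpus transformed with zero rejections the two
#' sides agree exactly and every accuracy is 100.
#'
#' The boundary conventions are deliberate and documented: hemoglobin
#' bounds 138 and 172 g/L are inclusive, the readmission window includes
#' day 30 exactly, and polypharmacy counts distinct medication codes (not
#' prescription rows).
#'
#' @param tables Named list of \code{source_table}s.
#' @param store A populated \code{\link{fhir_store}}.
#' @param schema The \code{\link{institution_schema}} of the tables.
#' @return Data.frame with columns \code{criterion_id}, \code{source_value},
#'   \code{transformed_value}, \code{accuracy_pct}.
#' @export
evaluate_utility <- function(tables, store, schema = institution_schema("A")) {
  rows <- lapply(UTILITY_CRITERIA, function(cr) {
    s <- utility_source(cr, tables, schema)
    t <- utility_store(cr, store)
    acc <- if (s == 0 && t == 0) 100 else 100 * (1 - abs(s - t) / max(s, 1))
    data.frame(criterion_id = cr, source_value = as.integer(s),
               transformed_value = as.integer(t), accuracy_pct = acc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
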