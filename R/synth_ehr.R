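# Seeded generator of two-institution-style tabular EHR extracts. Cohort
# criteria (COPD, polypharmacy, readmissions, hemoglobin range, top-5
# conditions) are planted with exact target counts, and invalid rows
# (missing id key, unparseable numeric, untranslatable code) can be planted
# at a configured rate — always in rows nothing references, so rejecting
# them never dangles a reference. The planted ledger is the ground truth
# every downstream count is audited against.

SYNTH_CRITERIA <- c("female_top5", "copd", "polypharmacy5", "readmit30",
                    "hgb_male_range")

COPD_CODES <- c("J44", "J44.0", "J44.1", "J44.9")

#' Column roles and gender codes of the two institution presets
#'
#' Preset "A" emulates a hospital EHR extract (Spanish-style H/M gender
#' codes, ISO dates); preset "B" a research-registry extract (numeric sex
#' codes, DD/MM/YYYY dates, different table and column names). Both ship
#' with matching mapping configurations under \code{extdata/mappings/}.
#'
#' @param institution "A" or "B".
#' @return List with \code{tables} (role -> table name), \code{columns}
#'   (role -> column name), \code{gender_codes} (local code -> FHIR
#'   administrative-gender code), \code{gender_system}, \code{date_format}
#'   and \code{unmapped_gender_code}.
#' @export
institution_schema <- function(institution = c("A", "B")) {
  institution <- match.arg(institution)
  if (institution == "A") {
    list(
      institution = "A",
      tables = c(patients = "patients", admissions = "admissions",
                 observations = "observations", conditions = "conditions",
                 prescriptions = "prescriptions"),
      columns = c(patient_id = "patientid", gender = "gender",
                  birthdate = "birthdate", admission_id = "admissionid",
                  admit_date = "admitdate", discharge_date = "dischargedate",
                  observation_id = "obsid", obs_code = "loinccode",
                  obs_value = "value", obs_unit = "unit", obs_date = "obsdate",
                  condition_id = "condid", condition_code = "icd10code",
                  onset_date = "onsetdate", prescription_id = "rxid",
                  med_code = "medcode", rx_date = "startdate"),
      gender_codes = c(H = "male", M = "female"),
      gender_system = "http://example.org/fhir/CodeSystem/local-gender-a",
      unmapped_gender_code = "X",
      date_format = "%Y-%m-%d"
    )
  } else {
    list(
      institution = "B",
      tables = c(patients = "subjects", admissions = "stays",
                 observations = "labs", conditions = "diagnoses",
                 prescriptions = "medications"),
      columns = c(patient_id = "subject_ref", gender = "sex_code",
                  birthdate = "dob", admission_id = "stay_id",
                  admit_date = "entry_date", discharge_date = "exit_date",
                  observation_id = "lab_id", obs_code = "test_loinc",
                  obs_value = "result", obs_unit = "result_unit",
                  obs_date = "test_date", condition_id = "dx_id",
                  condition_code = "dx_icd10", onset_date = "dx_date",
                  prescription_id = "med_id", med_code = "atc_code",
                  rx_date = "issued"),
      gender_codes = c(`1` = "male", `2` = "female"),
      gender_system = "http://example.org/fhir/CodeSystem/local-gender-b",
      unmapped_gender_code = "9",
      date_format = "%d/%m/%Y"
    )
  }
}

#' Synthetic-corpus configuration
#'
#' @param seed Master seed; per-table streams are derived from it, so adding
#'   a table never perturbs the others.
#' @param n_patients Number of patients (default 200: a desk-scale corpus
#'   that keeps all planted cohorts comfortably feasible).
#' @param planted Named list of exact target counts per criterion
#'   (\code{female_top5}, \code{copd}, \code{polypharmacy5},
#'   \code{readmit30}, \code{hgb_male_range}); defaults scale with
#'   \code{n_patients} (20/12.5/15/7.5/10 percent).
#' @param error_rate Fraction of rows planted with defects (0-1). Defect
#'   kinds cycle over untranslatable gender code, missing id key and
#'   unparseable numeric value.
#' @param institution "A" (hospital-like) or "B" (registry-like), see
#'   \code{\link{institution_schema}}.
#' @return A validated list of class \code{synth_config}.
#' @export
synth_config <- function(seed, n_patients = 200, planted = NULL,
                         error_rate = 0, institution = "A") {
  if (error_rate < 0 || error_rate > 1) {
    fc_stop("config", "error_rate must be in [0, 1]")
  }
  if (n_patients < 20) {
    fc_stop("config", "n_patients must be at least 20")
  }
  defaults <- list(
    female_top5 = round(0.20 * n_patients),
    copd = round(0.125 * n_patients),
    polypharmacy5 = round(0.15 * n_patients),
    readmit30 = round(0.075 * n_patients),
    hgb_male_range = round(0.10 * n_patients)
  )
  planted <- utils::modifyList(defaults, as.list(planted %||% list()))
  unknown <- setdiff(names(planted), SYNTH_CRITERIA)
  if (length(unknown) > 0) {
    fc_stop("config", paste("unknown planted criteria:",
                            paste(unknown, collapse = ",")))
  }
  n_childless <- max(2L, ceiling(0.06 * n_patients))
  eligible <- seq_len(n_patients - n_childless)
  females <- eligible[eligible %% 2 == 1]
  males <- eligible[eligible %% 2 == 0]
  if (planted$female_top5 > length(females)) {
    fc_stop("config", "planted female_top5 exceeds the number of female patients")
  }
  if (planted$hgb_male_range > length(males)) {
    fc_stop("config", "planted hgb_male_range exceeds the number of male patients")
  }
  for (cr in c("copd", "polypharmacy5", "readmit30")) {
    if (planted[[cr]] > length(eligible)) {
      fc_stop("config", sprintf("planted %s exceeds the eligible patient count", cr))
    }
    if (planted[[cr]] < 0) fc_stop("config", "planted counts must be >= 0")
  }
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 planted = planted, error_rate = error_rate,
                 institution = institution,
                 n_childless = as.integer(n_childless)),
            class = "synth_config")
}

sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 7919) %% 2147483646) + 1L
}

rand_dates <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic two-institution EHR extract
#'
#' Produces five tables (patients, admissions, observations, conditions,
#' prescriptions — named and coded per the institution preset) together
#' with the planted ledger: the exact qualifying row keys per cohort
#' criterion and the list of planted invalid rows. Same seed, same bytes.
#'
#' Construction guarantees, verifiable by direct recomputation from the
#' tables:
#' \itemize{
#'   \item exactly \code{planted$female_top5} female patients carry a
#'     condition among the 5 most frequent condition codes (the five
#'     "common" codes are frequency-dominant by a per-code cap on all other
#'     codes, ties impossible by construction);
#'   \item exactly \code{planted$copd} patients carry a J44-family code;
#'   \item exactly \code{planted$polypharmacy5} patients have >= 5 distinct
#'     medication codes; all others have <= 4;
#'   \item exactly \code{planted$readmit30} admissions start within 30 days
#'     (inclusive; one gap is forced to exactly 30) of the same patient's
#'     previous discharge; all other gaps are >= 31 days;
#'   \item exactly \code{planted$hgb_male_range} male patients have a LOINC
#'     718-7 observation valued in [138, 172] g/L; other males' hemoglobin
#'     values are kept outside [137.5, 172.5] so rounding cannot leak in.
#' }
#' Invalid rows are planted only in rows nothing references: untranslatable
#' gender codes go to childless patients, missing ids and unparseable
#' numerics to filler observations and to prescriptions of
#' non-polypharmacy patients.
#'
#' @param config A \code{\link{synth_config}} (or a seed, for defaults).
#' @return An object of class \code{synth_ehr}: list with \code{tables}
#'   (named list of \code{source_table}s), \code{ledger} (per-criterion
#'   qualifying keys, counts, and \code{invalid_rows}), \code{schema} and
#'   \code{config}.
#' @export
generate_synth_ehr <- function(config) {
  if (!inherits(config, "synth_config")) config <- synth_config(config)
  schema <- institution_schema(config$institution)
  n <- config$n_patients
  n_childless <- config$n_childless
  eligible <- seq_len(n - n_childless)
  childless <- setdiff(seq_len(n), eligible)
  females <- which(seq_len(n) %% 2 == 1)
  males <- which(seq_len(n) %% 2 == 0)
  pid <- sprintf("P%04d", seq_len(n))
  pk <- config$planted

  # -- patients ---------------------------------------------------------------
  set.seed(sub_seed(config$seed, 1))
  local_of <- stats::setNames(names(schema$gender_codes), schema$gender_codes)
  gender_local <- ifelse(seq_len(n) %in% females,
                         local_of[["female"]], local_of[["male"]])
  patients <- data.frame(
    patientid = pid,
    gender = gender_local,
    birthdate = format(rand_dates(n, "1930-01-01", "2000-12-31"), "%Y-%m-%d"),
    stringsAsFactors = FALSE
  )

  # -- planted cohorts --------------------------------------------------------
  set.seed(sub_seed(config$seed, 2))
  f5_set <- sort(sample(intersect(females, eligible), pk$female_top5))
  copd_set <- sort(sample(eligible, pk$copd))
  poly_set <- sort(sample(eligible, pk$polypharmacy5))
  readmit_set <- sort(sample(eligible, pk$readmit30))
  hgb_set <- sort(sample(intersect(males, eligible), pk$hgb_male_range))
  male_common <- sort(sample(setdiff(intersect(males, eligible), integer(0)),
                             min(20L, length(intersect(males, eligible)))))

  # -- admissions -------------------------------------------------------------
  set.seed(sub_seed(config$seed, 3))
  adm <- list()
  readmit_adm_ids <- character(0)
  adm_of_patient <- vector("list", n)
  next_adm <- 1L
  push_adm <- function(p, start, end) {
    id <- sprintf("A%05d", next_adm)
    next_adm <<- next_adm + 1L
    adm[[length(adm) + 1L]] <<- data.frame(
      admissionid = id, patientid = pid[p],
      admitdate = format(start, "%Y-%m-%d"),
      dischargedate = format(end, "%Y-%m-%d"), stringsAsFactors = FALSE)
    adm_of_patient[[p]] <<- c(adm_of_patient[[p]], id)
    id
  }
  forced_30 <- FALSE
  for (p in eligible) {
    start <- rand_dates(1, "2023-01-01", "2023-09-30")
    dur <- sample(1:14, 1)
    push_adm(p, start, start + dur)
    if (p %in% readmit_set) {
      gap <- if (!forced_30) { forced_30 <- TRUE; 30L } else sample(1:30, 1)
      s2 <- start + dur + gap
      id2 <- push_adm(p, s2, s2 + sample(1:14, 1))
      readmit_adm_ids <- c(readmit_adm_ids, id2)
    } else if (stats::runif(1) < 0.3) {
      s2 <- start + dur + sample(31:120, 1)
      push_adm(p, s2, s2 + sample(1:14, 1))
    }
  }
  admissions <- do.call(rbind, adm)

  # -- conditions -------------------------------------------------------------
  set.seed(sub_seed(config$seed, 4))
  common_codes <- c("I10", "E11", "E78", "K21", "M54")
  rare_pool <- c("A09", "B01", "C34.1", "D50", "E03.9", "F32", "G40", "H52.1",
                 "I48", "J18.9", "K29.7", "L40", "M17.1", "N39.0", "R10.4",
                 "S72.0", "T78.4", "Z51.1", "G43", "H40", "I63.9", "K80.2",
                 "L20", "M81.0", "N20.0", "E66", "F41.1", "G47.3", "J30.1",
                 "K57.3")
  cond <- list()
  next_cond <- 1L
  push_cond <- function(p, code) {
    id <- sprintf("C%05d", next_cond)
    next_cond <<- next_cond + 1L
    cond[[length(cond) + 1L]] <<- data.frame(
      condid = id, patientid = pid[p], icd10code = code,
      onsetdate = format(rand_dates(1, "2023-01-01", "2024-12-31"), "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }
  common_carriers <- c(f5_set, setdiff(male_common, integer(0)))
  for (i in seq_along(common_carriers)) {
    push_cond(common_carriers[i], common_codes[(i - 1L) %% 5L + 1L])
  }
  min_common <- floor(length(common_carriers) / 5)
  if (min_common < 2 || ceiling(length(copd_set) / 4) >= min_common) {
    fc_stop("config", paste(
      "planted counts make the top-5 condition codes ambiguous:",
      "too few common-code carriers relative to the COPD cohort"))
  }
  for (i in seq_along(copd_set)) {
    push_cond(copd_set[i], COPD_CODES[(i - 1L) %% 4L + 1L])
  }
  # rare background conditions, capped per code below the common-code floor
  rare_cap <- max(1L, min_common - 1L)
  rare_counts <- stats::setNames(integer(length(rare_pool)), rare_pool)
  ptr <- 0L
  for (p in eligible) {
    for (k in seq_len(sample(0:2, 1))) {
      placed <- FALSE
      for (try in seq_along(rare_pool)) {
        ptr <- ptr %% length(rare_pool) + 1L
        code <- rare_pool[ptr]
        if (rare_counts[[code]] < rare_cap) {
          # a rare code on an f5/common-carrying patient is fine; a COMMON
          # code must never reach a female outside f5_set
          push_cond(p, code)
          rare_counts[[code]] <- rare_counts[[code]] + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
  }
  conditions <- do.call(rbind, cond)

  # -- prescriptions ----------------------------------------------------------
  set.seed(sub_seed(config$seed, 5))
  med_pool <- c("A02BC02", "A10BA02", "B01AC06", "C03CA01", "C07AB07",
                "C09AA05", "C10AA01", "J01CA04", "M01AE01", "N02BE01",
                "N05BA06", "R03AC02", "A12AA04", "C08CA01", "N06AB06",
                "H03AA01", "L04AX03", "R06AE07", "S01ED51", "B03BA01")
  rx <- list()
  next_rx <- 1L
  rx_rows_nonpoly <- integer(0)
  push_rx <- function(p, code, poly) {
    id <- sprintf("R%05d", next_rx)
    next_rx <<- next_rx + 1L
    rx[[length(rx) + 1L]] <<- data.frame(
      rxid = id, patientid = pid[p], medcode = code,
      startdate = format(rand_dates(1, "2023-01-01", "2024-12-31"), "%Y-%m-%d"),
      stringsAsFactors = FALSE)
    if (!poly) rx_rows_nonpoly <<- c(rx_rows_nonpoly, length(rx))
  }
  for (p in eligible) {
    if (p %in% poly_set) {
      k <- 5L + (p %% 3L)
      for (code in sample(med_pool, k)) push_rx(p, code, poly = TRUE)
    } else {
      k <- sample(0:4, 1)
      if (k > 0) for (code in sample(med_pool, k)) push_rx(p, code, poly = FALSE)
    }
  }
  prescriptions <- do.call(rbind, rx)

  # -- observations -----------------------------------------------------------
  set.seed(sub_seed(config$seed, 6))
  obs <- list()
  next_obs <- 1L
  filler_rows <- integer(0)
  push_obs <- function(p, code, value, unit, filler) {
    id <- sprintf("O%05d", next_obs)
    next_obs <<- next_obs + 1L
    adm_id <- ""
    own <- adm_of_patient[[p]]
    if (length(own) > 0 && stats::runif(1) < 0.5) adm_id <- sample(own, 1)
    obs[[length(obs) + 1L]] <<- data.frame(
      obsid = id, patientid = pid[p], admissionid = adm_id, loinccode = code,
      value = as.character(value), unit = unit,
      obsdate = format(rand_dates(1, "2023-01-01", "2024-12-31"), "%Y-%m-%d"),
      stringsAsFactors = FALSE)
    if (filler) filler_rows <<- c(filler_rows, length(obs))
  }
  for (p in hgb_set) {
    push_obs(p, "718-7", round(stats::runif(1, 138, 172), 1), "g/L", FALSE)
  }
  for (p in setdiff(intersect(males, eligible), hgb_set)) {
    if (stats::runif(1) < 0.6) {
      v <- if (stats::runif(1) < 0.5) round(stats::runif(1, 100, 137.4), 1)
           else round(stats::runif(1, 172.6, 200), 1)
      push_obs(p, "718-7", v, "g/L", FALSE)
    }
  }
  for (p in intersect(females, eligible)) {
    if (stats::runif(1) < 0.5) {
      push_obs(p, "718-7", round(stats::runif(1, 100, 200), 1), "g/L", FALSE)
    }
  }
  filler_pool <- list(list("2160-0", "umol/L", 40, 120),
                      list("2093-3", "mmol/L", 3, 8),
                      list("8867-4", "/min", 50, 110))
  for (p in eligible) {
    for (k in seq_len(sample(1:3, 1))) {
      f <- filler_pool[[sample(3, 1)]]
      push_obs(p, f[[1]], round(stats::runif(1, f[[3]], f[[4]]), 1), f[[2]], TRUE)
    }
  }
  observations <- do.call(rbind, obs)

  # -- defect planting --------------------------------------------------------
  set.seed(sub_seed(config$seed, 7))
  total_rows <- nrow(patients) + nrow(admissions) + nrow(observations) +
    nrow(conditions) + nrow(prescriptions)
  k_err <- round(config$error_rate * total_rows)
  invalid <- list()
  if (k_err > 0) {
    k_gender <- min(length(childless), k_err %/% 4L)
    rest <- k_err - k_gender
    k_unp <- min(length(filler_rows) %/% 2L, (rest + 1L) %/% 2L)
    rest <- rest - k_unp
    k_mid_obs <- min(length(filler_rows) - k_unp, (rest + 1L) %/% 2L)
    k_mid_rx <- rest - k_mid_obs
    if (k_mid_rx > length(rx_rows_nonpoly)) {
      fc_stop("config", "error_rate too high for the corpus size: not enough unreferenced rows to corrupt")
    }
    for (i in seq_len(k_gender)) {
      p <- childless[i]
      patients$gender[p] <- schema$unmapped_gender_code
      invalid[[length(invalid) + 1L]] <- data.frame(
        table = schema$tables[["patients"]], row_index = p - 1L,
        defect_kind = "untranslatable-code", stringsAsFactors = FALSE)
    }
    corrupt_obs <- sample(filler_rows, k_unp + k_mid_obs)
    for (i in seq_len(k_unp)) {
      r <- corrupt_obs[i]
      observations$value[r] <- "#err#"
      invalid[[length(invalid) + 1L]] <- data.frame(
        table = schema$tables[["observations"]], row_index = r - 1L,
        defect_kind = "unparseable-value", stringsAsFactors = FALSE)
    }
    for (i in seq_len(k_mid_obs)) {
      r <- corrupt_obs[k_unp + i]
      observations$obsid[r] <- ""
      invalid[[length(invalid) + 1L]] <- data.frame(
        table = schema$tables[["observations"]], row_index = r - 1L,
        defect_kind = "missing-id-key", stringsAsFactors = FALSE)
    }
    corrupt_rx <- sample(rx_rows_nonpoly, k_mid_rx)
    for (r in corrupt_rx) {
      prescriptions$rxid[r] <- ""
      invalid[[length(invalid) + 1L]] <- data.frame(
        table = schema$tables[["prescriptions"]], row_index = r - 1L,
        defect_kind = "missing-id-key", stringsAsFactors = FALSE)
    }
  }
  invalid_rows <- if (length(invalid) == 0) {
    data.frame(table = character(0), row_index = integer(0),
               defect_kind = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, invalid)

  ledger <- list(
    female_top5 = pid[f5_set],
    copd = pid[copd_set],
    polypharmacy5 = pid[poly_set],
    readmit30 = readmit_adm_ids,
    hgb_male_range = pid[hgb_set],
    top5_codes = common_codes,
    counts = c(female_top5 = length(f5_set), copd = length(copd_set),
               polypharmacy5 = length(poly_set),
               readmit30 = length(readmit_adm_ids),
               hgb_male_range = length(hgb_set)),
    invalid_rows = invalid_rows
  )

  tables <- list(patients = patients, admissions = admissions,
                 observations = observations, conditions = conditions,
                 prescriptions = prescriptions)
  tables <- rename_to_schema(tables, schema)

  structure(list(tables = tables, ledger = ledger, schema = schema,
                 config = config),
            class = "synth_ehr")
}

#' Rename canonical tables/columns/dates into the institution dialect
#' @noRd
rename_to_schema <- function(tables, schema) {
  cols <- schema$columns
  canon_cols <- list(
    patients = c("patientid", "gender", "birthdate"),
    admissions = c("admissionid", "patientid", "admitdate", "dischargedate"),
    observations = c("obsid", "patientid", "admissionid", "loinccode",
                     "value", "unit", "obsdate"),
    prescriptions = c("rxid", "patientid", "medcode", "startdate"),
    conditions = c("condid", "patientid", "icd10code", "onsetdate")
  )
  role_of <- c(patientid = "patient_id", gender = "gender",
               birthdate = "birthdate", admissionid = "admission_id",
               admitdate = "admit_date", dischargedate = "discharge_date",
               obsid = "observation_id", loinccode = "obs_code",
               value = "obs_value", unit = "obs_unit", obsdate = "obs_date",
               condid = "condition_id", icd10code = "condition_code",
               onsetdate = "onset_date", rxid = "prescription_id",
               medcode = "med_code", startdate = "rx_date")
  date_cols <- c("birthdate", "admitdate", "dischargedate", "obsdate",
                 "onsetdate", "startdate")
  out <- list()
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (schema$date_format != "%Y-%m-%d") {
      for (dc in intersect(date_cols, names(df))) {
        ok <- !is.na(df[[dc]]) & nzchar(df[[dc]])
        df[[dc]][ok] <- format(as.Date(df[[dc]][ok]), schema$date_format)
      }
    }
    names(df) <- unname(cols[role_of[names(df)]])
    out[[schema$tables[[nm]]]] <- new_source_table(df, schema$tables[[nm]])
  }
  out
}

#' @export
print.synth_ehr <- function(x, ...) {
  cat("<synth_ehr> institution", x$schema$institution, "- seed",
      x$config$seed, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-14s %d row(s)\n", nm, nrow(x$tables[[nm]])))
  }
  cat("  planted:",
      paste(sprintf("%s=%d", names(x$ledger$counts), x$ledger$counts),
            collapse = ", "), "\n")
  cat("  invalid rows:", nrow(x$ledger$invalid_rows), "\n")
  invisible(x)
}

#' Write the synthetic tables as CSV files
#'
#' One UTF-8 comma-separated file per table, header row first, no quoting
#' (cell values are quote-free by construction). Byte-identical for a given
#' seed.
#'
#' @param synth A \code{\link{generate_synth_ehr}} result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synth_csv <- function(synth, dir) {
  stopifnot(inherits(synth, "synth_ehr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(synth$tables)) {
    df <- synth$tables[[nm]]
    class(df) <- "data.frame"
    df[is.na(df)] <- ""
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, eol = "\n")
  }
  invisible(dir)
}
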