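# Boundary-convention fixtures are built by hand; the institution-A schema
# names are used throughout.

mini_tables <- function(patients, conditions = NULL, prescriptions = NULL,
                        admissions = NULL, observations = NULL) {
  empty <- list(
    conditions = data.frame(condid = character(0), patientid = character(0),
                            icd10code = character(0), onsetdate = character(0)),
    prescriptions = data.frame(rxid = character(0), patientid = character(0),
                               medcode = character(0), startdate = character(0)),
    admissions = data.frame(admissionid = character(0), patientid = character(0),
                            admitdate = character(0), dischargedate = character(0)),
    observations = data.frame(obsid = character(0), patientid = character(0),
                              admissionid = character(0), loinccode = character(0),
                              value = character(0), unit = character(0),
                              obsdate = character(0)))
  tabs <- list(patients = patients,
               conditions = conditions %||% empty$conditions,
               prescriptions = prescriptions %||% empty$prescriptions,
               admissions = admissions %||% empty$admissions,
               observations = observations %||% empty$observations)
  lapply(stats::setNames(names(tabs), names(tabs)), function(nm)
    df_source_table(tabs[[nm]], nm))
}

two_patients <- data.frame(patientid = c("p1", "p2"), gender = c("M", "H"),
                           birthdate = c("1950-01-01", "1960-01-01"))

test_that("COPD membership is exact-code, no prefix expansion", {
  conds <- data.frame(condid = c("c1", "c2", "c3"),
                      patientid = c("p1", "p2", "p2"),
                      icd10code = c("J45", "J44.1", "J44.12"),
                      onsetdate = "2023-01-01")
  tabs <- mini_tables(two_patients, conditions = conds)
  # J45 excluded, J44.1 included, J44.12 is not in the four-code set
  expect_identical(utility_source("copd", tabs), 1L)
})

test_that("polypharmacy counts distinct medication codes with an inclusive 5 bound", {
  rx <- data.frame(
    rxid = sprintf("r%d", 1:11),
    patientid = c(rep("p1", 6), rep("p2", 5)),
    medcode = c("A", "B", "C", "D", "D", "D",      # p1: 4 distinct
                "A", "B", "C", "D", "E"),          # p2: 5 distinct
    startdate = "2023-01-01")
  tabs <- mini_tables(two_patients, prescriptions = rx)
  expect_identical(utility_source("polypharmacy5", tabs), 1L)
})

test_that("the readmission window includes day 30 and excludes day 31", {
  adm <- data.frame(
    admissionid = c("a1", "a2", "a3", "a4"),
    patientid = c("p1", "p1", "p2", "p2"),
    admitdate = c("2023-01-01", "2023-02-09", "2023-01-01", "2023-02-10"),
    dischargedate = c("2023-01-10", "2023-02-15", "2023-01-10", "2023-02-20"))
  # p1: gap 30 days -> counted; p2: gap 31 days -> not
  tabs <- mini_tables(two_patients, admissions = adm)
  expect_identical(utility_source("readmit30", tabs), 1L)

  single <- data.frame(admissionid = c("a1", "a2"), patientid = c("p1", "p2"),
                       admitdate = "2023-01-01", dischargedate = "2023-01-05")
  expect_identical(utility_source("readmit30",
                                  mini_tables(two_patients, admissions = single)),
                   0L)
})

test_that("hemoglobin bounds are inclusive and gender-filtered", {
  obs <- data.frame(
    obsid = sprintf("o%d", 1:4),
    patientid = c("p2", "p2", "p2", "p1"),
    admissionid = "",
    loinccode = "718-7",
    value = c("138", "172", "137.9", "150"),
    unit = "g/L", obsdate = "2023-01-01")
  # p2 is male (H): 138 and 172 qualify; p1 is female: 150 does not count
  tabs <- mini_tables(two_patients, observations = obs)
  expect_identical(utility_source("hgb_male_range", tabs), 1L)

  out <- obs[3, , drop = FALSE]  # only the out-of-range male value
  expect_identical(utility_source("hgb_male_range",
                                  mini_tables(two_patients, observations = out)),
                   0L)
})

test_that("female_top5 handles empty and all-male corners", {
  expect_identical(utility_source("female_top5", mini_tables(two_patients)), 0L)
  males <- data.frame(patientid = c("p1", "p2"), gender = c("H", "H"),
                      birthdate = "1950-01-01")
  conds <- data.frame(condid = "c1", patientid = "p1", icd10code = "I10",
                      onsetdate = "2023-01-01")
  expect_identical(utility_source("female_top5",
                                  mini_tables(males, conditions = conds)), 0L)
})

test_that("a randomized admission schedule matches a quadratic all-pairs oracle", {
  set.seed(99)
  rows <- list()
  for (p in sprintf("q%02d", 1:50)) {
    n_adm <- sample(1:4, 1)
    start <- as.Date("2023-01-01") + sample(0:100, 1)
    for (k in seq_len(n_adm)) {
      end <- start + sample(1:10, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        admissionid = sprintf("%s-%d", p, k), patientid = p,
        admitdate = format(start, "%Y-%m-%d"),
        dischargedate = format(end, "%Y-%m-%d"))
      start <- end + sample(1:60, 1)
    }
  }
  adm <- do.call(rbind, rows)

  # independent oracle: for every admission, find the most recent prior
  # discharge of the same patient by scanning all pairs
  oracle <- 0L
  for (i in seq_len(nrow(adm))) {
    prior <- adm[adm$patientid == adm$patientid[i] &
                   as.Date(adm$admitdate) < as.Date(adm$admitdate[i]), ]
    if (nrow(prior) == 0) next
    gap <- as.integer(as.Date(adm$admitdate[i]) -
                        max(as.Date(prior$dischargedate)))
    if (gap >= 0 && gap <= 30) oracle <- oracle + 1L
  }
  pats <- data.frame(patientid = unique(adm$patientid), gender = "H",
                     birthdate = "1950-01-01")
  tabs <- mini_tables(pats, admissions = adm)
  expect_identical(utility_source("readmit30", tabs), oracle)
})

test_that("store-side criteria equal a brute-force scan of persisted resources", {
  pipe <- small_pipeline()
  store <- pipe$store

  # oracle for the hemoglobin criterion: linear scan of all resources
  male_ids <- vapply(Filter(function(r) identical(r$gender, "male"),
                            store_resources(store, "Patient")), `[[`, "", "id")
  hits <- character(0)
  for (r in store_resources(store, "Observation")) {
    code <- r$code$coding[[1]]$code
    v <- r$valueQuantity$value
    if (identical(code, "718-7") && !is.null(v) && v >= 138 && v <= 172) {
      hits <- c(hits, sub("^Patient/", "", r$subject$reference))
    }
  }
  expect_identical(utility_store("hgb_male_range", store),
                   length(intersect(unique(hits), male_ids)))

  # oracle for COPD: linear scan of Condition codes
  copd_hits <- character(0)
  for (r in store_resources(store, "Condition")) {
    if (r$code$coding[[1]]$code %in% c("J44", "J44.0", "J44.1", "J44.9")) {
      copd_hits <- c(copd_hits, sub("^Patient/", "", r$subject$reference))
    }
  }
  expect_identical(utility_store("copd", store),
                   length(unique(copd_hits)))
})

test_that("both sides agree with the planted ledger on the clean corpus", {
  pipe <- small_pipeline()
  u <- evaluate_utility(pipe$synth$tables, pipe$store, pipe$synth$schema)
  expect_identical(u$source_value,
                   unname(as.integer(pipe$synth$ledger$counts[u$criterion_id])))
  expect_identical(u$transformed_value, u$source_value)
  expect_true(all(u$accuracy_pct == 100))
})
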