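test_that("hash_id is deterministic, type-salted and matches an independent digest", {
  expect_identical(hash_id("Patient", "p001"), hash_id("Patient", "p001"))
  expect_false(hash_id("Patient", "p1") == hash_id("Observation", "p1"))

  # independent oracle: openssl's SHA-256 of the same salted string
  skip_if_not_installed("openssl")
  expect_identical(hash_id("Patient", "p001"),
                   substr(as.character(openssl::sha256("Patient|p001")), 1, 64))

  expect_error(hash_id("Patient", ""), class = "missing_id_key")
  expect_error(hash_id("Patient", "   "), class = "missing_id_key")
})

test_that("references are built with the shared hashing scheme", {
  config <- pkg_mapping("a")
  profiles <- pkg_profiles()
  obs_rm <- config$resource_mappings[[3]]
  prof <- find_profile(profiles, "Observation", obs_rm$profile_url)
  row <- list(obsid = "o1", patientid = "p1", admissionid = NA,
              loinccode = "718-7", value = "142", unit = "g/L",
              obsdate = "2023-05-01")
  res <- transform_row(obs_rm, row, prof, pkg_index())
  expect_identical(res$subject$reference,
                   paste0("Patient/", hash_id("Patient", "p1")))
  expect_identical(res$id, hash_id("Observation", "o1"))
  expect_null(res$encounter)  # null foreign key is skipped, not an error
  expect_identical(res$valueQuantity$value, 142)
  expect_identical(res$code$coding[[1]]$system, "http://loinc.org")
})

test_that("a full synthetic patient row becomes the expected resource document", {
  config <- pkg_mapping("a")
  profiles <- pkg_profiles()
  rm <- config$resource_mappings[[1]]
  prof <- find_profile(profiles, "Patient", rm$profile_url)
  res <- transform_row(rm, list(patientid = "P0001", gender = "H",
                                birthdate = "1950-01-02"),
                       prof, pkg_index())
  expected <- list(
    resourceType = "Patient",
    id = hash_id("Patient", "P0001"),
    meta = list(profile = list(
      "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile")),
    gender = "male",
    birthDate = "1950-01-02")
  expect_identical(res, expected)
})

test_that("dates are normalized to ISO 8601 and bad cells raise typed errors", {
  config <- pkg_mapping("b")
  profiles <- pkg_profiles()
  rm <- config$resource_mappings[[1]]
  prof <- find_profile(profiles, "Patient", rm$profile_url)
  res <- transform_row(rm, list(subject_ref = "P0001", sex_code = "2",
                                dob = "02/01/1950"), prof, pkg_index())
  expect_identical(res$birthDate, "1950-01-02")
  expect_identical(res$gender, "female")

  obs_rm <- pkg_mapping("a")$resource_mappings[[3]]
  obs_prof <- find_profile(profiles, "Observation", obs_rm$profile_url)
  row <- list(obsid = "o1", patientid = "p1", admissionid = NA,
              loinccode = "718-7", value = "#err#", unit = "g/L",
              obsdate = "2023-05-01")
  expect_error(transform_row(obs_rm, row, obs_prof, pkg_index()),
               class = "unparseable_value")

  expect_error(transform_row(obs_rm, utils::modifyList(row, list(obsid = "")),
                             obs_prof, pkg_index()),
               class = "missing_id_key")
  expect_error(
    transform_row(rm, list(subject_ref = "P1", sex_code = "9", dob = NA),
                  prof, pkg_index()),
    class = "untranslatable_code")
})

test_that("empty tables yield an empty report and no session metadata", {
  profiles <- pkg_profiles()
  store <- fhir_store(profiles, pkg_valuesets())
  empty <- df_source_table(
    data.frame(patientid = character(0), gender = character(0),
               birthdate = character(0)), "patients")
  config <- mapping_config(list(pkg_mapping("a")$resource_mappings[[1]]))
  report <- run_session(config, list(patients = empty), profiles,
                        pkg_index(), store)
  expect_length(report$created_ids, 0)
  expect_identical(nrow(report$rejected), 0L)
  expect_true(is.na(report$provenance_id))
  expect_length(store_resources(store, "Provenance"), 0)
})

test_that("rows collapsing to an empty resource are rejected, not written", {
  profiles <- pkg_profiles()
  lax <- build_constraint_tree(tiny_patient_profile_doc(gender_min = 0L))
  profs <- c(profiles, list(lax))
  names(profs)[length(profs)] <- lax$canonical_url
  store <- fhir_store(profs, pkg_valuesets())
  table <- df_source_table(
    data.frame(patientid = "p1", gender = "NA", birthdate = ""), "patients")
  config <- mapping_config(list(resource_mapping(
    "patients", "Patient", "patientid",
    list(element_mapping("Patient.gender", "value", source_column = "gender",
                         translation = translation_spec(
                           "http://example.org/fhir/CodeSystem/local-gender-a",
                           "http://hl7.org/fhir/administrative-gender")),
         element_mapping("Patient.birthDate", "value",
                         source_column = "birthdate")),
    profile_url = lax$canonical_url)))
  report <- run_session(config, list(patients = table), profs, pkg_index(),
                        store)
  expect_identical(nrow(report$rejected), 1L)
  expect_identical(report$rejected$reason_code, "validation-failed")
  expect_length(store_resources(store, "Patient"), 0)
})

test_that("count conservation holds per table and metadata is written once", {
  pipe <- small_pipeline()
  report <- pipe$report
  synth <- pipe$synth
  config <- pkg_mapping("a")
  type_of <- stats::setNames(
    vapply(config$resource_mappings, `[[`, "", "resource_type"),
    vapply(config$resource_mappings, `[[`, "", "source_table"))
  for (tname in names(synth$tables)) {
    n_created <- report$created[[type_of[[tname]]]]
    n_rejected <- sum(report$rejected$table == tname)
    expect_identical(n_created + n_rejected, nrow(synth$tables[[tname]]),
                     info = tname)
  }
  expect_length(store_resources(pipe$store, "Provenance"), 1)
  expect_length(store_resources(pipe$store, "DocumentManifest"), 1)

  prov <- store_get(pipe$store, "Provenance", report$provenance_id)
  expect_length(prov$target, length(report$created_ids))
})

test_that("manifest author and license round-trip verbatim", {
  pipe <- run_pipeline(seed = 5, n_patients = 30, author = "Jane Steward",
                       license = "CC-BY-4.0")
  man <- store_get(pipe$store, "DocumentManifest", pipe$report$manifest_id)
  expect_identical(man$author[[1]]$display, "Jane Steward")
  expect_identical(man$description, "CC-BY-4.0")
  expect_length(man$content, length(pipe$report$created_ids))
})

test_that("re-running a session is idempotent in ids and bodies", {
  pipe1 <- run_pipeline(seed = 9, n_patients = 30)
  pipe2 <- run_pipeline(seed = 9, n_patients = 30)
  expect_identical(sort(pipe1$report$created_ids),
                   sort(pipe2$report$created_ids))
  strip_meta <- function(r) { r$meta$lastUpdated <- NULL; r }
  for (r in store_resources(pipe1$store)) {
    r2 <- store_get(pipe2$store, r$resourceType, r$id)
    if (r$resourceType == "Provenance") { r$recorded <- NULL; r2$recorded <- NULL }
    if (r$resourceType == "DocumentManifest") { r$created <- NULL; r2$created <- NULL }
    expect_identical(strip_meta(r), strip_meta(r2))
  }

  # re-running into the same store bumps versions instead of duplicating
  n_before <- length(store_resources(pipe1$store))
  run_session(pkg_mapping("a"), generate_synth_ehr(synth_config(9, 30))$tables,
              pipe1$profiles, pkg_index(), pipe1$store)
  expect_identical(length(store_resources(pipe1$store)), n_before)
  some <- store_resources(pipe1$store, "Patient")[[1]]
  expect_identical(some$meta$versionId, "2")
})

test_that("each session gets its own Provenance resource", {
  profiles <- pkg_profiles()
  store <- fhir_store(profiles, pkg_valuesets())
  idx <- pkg_index()
  config <- pkg_mapping("a")
  run_session(config, generate_synth_ehr(synth_config(3, 30))$tables,
              profiles, idx, store)
  run_session(config, generate_synth_ehr(synth_config(3, 40))$tables,
              profiles, idx, store)
  expect_length(store_resources(store, "Provenance"), 2)
})

test_that("a session never starts on a mapping with blocking issues", {
  profiles <- pkg_profiles()
  store <- fhir_store(profiles, pkg_valuesets())
  table <- df_source_table(
    data.frame(patientid = "p1", gender = "H", birthdate = "1950-01-01"),
    "patients")
  config <- mapping_config(list(resource_mapping(
    "patients", "Patient", "patientid",
    list(element_mapping("Patient.birthDate", "value",
                         source_column = "birthdate")),
    profile_url = "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile")))
  expect_error(run_session(config, list(patients = table), profiles,
                           pkg_index(), store),
               class = "precondition")
  expect_length(store_resources(store), 0)
})
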