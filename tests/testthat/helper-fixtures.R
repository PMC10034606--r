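# Shared fixtures, built in code. Conformance artifacts come from the
# package's shipped extdata; small hand-rolled documents cover edge cases.

read_fixture_json <- function(...) {
  jsonlite::read_json(fhircurate_extdata(...), simplifyVector = FALSE)
}

pkg_profiles <- function() load_profiles(fhircurate_extdata("profiles"))
pkg_valuesets <- function() load_valuesets(fhircurate_extdata("terminology"))
pkg_index <- function() index_concept_maps(fhircurate_extdata("terminology"))
pkg_mapping <- function(institution = "a") {
  load_mapping(fhircurate_extdata("mappings",
                                  paste0("institution-", institution, ".json")))
}

#' A minimal CapabilityStatement document
tiny_caps_doc <- function() {
  list(
    resourceType = "CapabilityStatement",
    fhirVersion = "4.0.1",
    rest = list(list(
      mode = "server",
      resource = list(
        list(type = "Patient",
             supportedProfile = list("http://example.org/fhir/StructureDefinition/PatientProfile"),
             interaction = list(list(code = "create"), list(code = "search-type"))),
        list(type = "Observation",
             interaction = list(list(code = "read")))
      )
    ))
  )
}

#' A minimal snapshot-bearing Patient StructureDefinition
tiny_patient_profile_doc <- function(gender_min = 1L) {
  list(
    resourceType = "StructureDefinition",
    url = "http://example.org/fhir/StructureDefinition/TinyPatient",
    type = "Patient",
    snapshot = list(element = list(
      list(path = "Patient", min = 0L, max = "*"),
      list(path = "Patient.gender", min = gender_min, max = "1",
           type = list(list(code = "code")),
           binding = list(strength = "required",
                          valueSet = "http://hl7.org/fhir/ValueSet/administrative-gender")),
      list(path = "Patient.birthDate", min = 0L, max = "1",
           type = list(list(code = "date")))
    ))
  )
}

#' Write a data.frame as a CSV source table on disk
write_csv_fixture <- function(df, name = "table") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Build a source_table directly from a data.frame (no disk round trip)
df_source_table <- function(df, name) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  t <- open_source(path)[[1]]
  attr(t, "table_name") <- name
  t
}

#' Run the full pipeline on a seeded synthetic corpus
run_pipeline <- function(seed = 42, n_patients = 200, error_rate = 0,
                         institution = "A", author = "Data Steward",
                         license = "CC-BY-4.0") {
  synth <- generate_synth_ehr(synth_config(seed, n_patients,
                                           error_rate = error_rate,
                                           institution = institution))
  profiles <- pkg_profiles()
  store <- fhir_store(profiles, pkg_valuesets())
  report <- run_session(pkg_mapping(tolower(institution)), synth$tables,
                        profiles, pkg_index(), store,
                        author = author, license = license)
  list(synth = synth, store = store, report = report, profiles = profiles)
}

#' A small pipeline shared by several test files (60 patients, no defects)
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(seed = 7, n_patients = 60)
    cache
  }
})
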