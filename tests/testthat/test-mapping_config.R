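test_that("mapping documents round-trip through save and load", {
  config <- mapping_config(list(
    resource_mapping("patients", "Patient", "patientid", list(
      element_mapping("Patient.gender", "value", source_column = "gender",
                      translation = translation_spec(
                        "http://example.org/fhir/CodeSystem/local-gender-a",
                        "http://hl7.org/fhir/administrative-gender")),
      element_mapping("Patient.birthDate", "value", source_column = "birthdate")
    ), profile_url = "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile")
  ))
  json <- save_mapping(config)
  expect_identical(load_mapping(json), config)

  # stability: a second save of the loaded object is byte-identical
  expect_identical(save_mapping(load_mapping(json)), json)
})

test_that("schema violations on load name the offending JSON pointer", {
  bad <- '{"version":"1.0","fhir_endpoint":"embedded","resource_mappings":
    [{"source_table":"patients","resource_type":"Patient",
      "element_mappings":[]}]}'
  err <- expect_error(load_mapping(bad), class = "mapping_parse")
  expect_match(conditionMessage(err), "/resource_mappings/0/id_columns")

  expect_error(load_mapping('{"version":"1.0"}'), class = "mapping_parse")
  err2 <- expect_error(
    load_mapping('{"version":"1.0","fhir_endpoint":"embedded",
      "resource_mappings":[{"source_table":"t","resource_type":"Patient",
      "id_columns":["a"],"element_mappings":[{"target_path":"Patient.x",
      "kind":"bogus"}]}]}'),
    class = "mapping_parse")
  expect_match(conditionMessage(err2), "element_mappings/0/kind")
})

test_that("the shipped institution mapping loads into the expected object graph", {
  config <- pkg_mapping("a")
  expect_s3_class(config, "mapping_config")
  expect_length(config$resource_mappings, 5)

  pat <- config$resource_mappings[[1]]
  expect_identical(pat$source_table, "patients")
  expect_identical(pat$id_columns, "patientid")
  gender <- pat$element_mappings[[1]]
  expect_identical(gender$target_path, "Patient.gender")
  expect_identical(gender$translation$target_system,
                   "http://hl7.org/fhir/administrative-gender")

  obs <- config$resource_mappings[[3]]
  subj <- Filter(function(e) e$target_path == "Observation.subject",
                 obs$element_mappings)[[1]]
  expect_identical(subj$kind, "reference")
  expect_identical(subj$reference_target, "Patient")
})

test_that("static checks flag missing-required, unknown paths/columns and duplicates", {
  profiles <- pkg_profiles()
  patient_prof <- profiles[["http://example.org/fhir/StructureDefinition/SyntheticPatientProfile"]]
  table <- df_source_table(
    data.frame(patientid = "p1", gender = "H", birthdate = "1950-01-01"),
    "patients")

  # omitting a required element: exactly one missing-required at that path
  rm_nogender <- resource_mapping("patients", "Patient", "patientid", list(
    element_mapping("Patient.birthDate", "value", source_column = "birthdate")))
  issues <- check_mapping(rm_nogender, patient_prof, table)
  miss <- issues[issues$code == "missing-required", ]
  expect_identical(nrow(miss), 1L)
  expect_identical(miss$target_path, "Patient.gender")

  # an unconstrained profile with no mappings raises no errors
  lax <- build_constraint_tree(tiny_patient_profile_doc(gender_min = 0L))
  lax_issues <- check_mapping(
    resource_mapping("patients", "Patient", "patientid", list()), lax, table)
  expect_false(any(lax_issues$severity == "error"))

  # unknown target path and unknown source column are errors
  rm_bad <- resource_mapping("patients", "Patient", "patientid", list(
    element_mapping("Patient.gender", "value", source_column = "gender"),
    element_mapping("Patient.shoeSize", "value", source_column = "gender"),
    element_mapping("Patient.birthDate", "value", source_column = "nope")))
  bad <- check_mapping(rm_bad, patient_prof, table)
  expect_true("unknown-path" %in% bad$code)
  expect_true("unknown-column" %in% bad$code)

  dup <- check_mapping(resource_mapping("patients", "Patient", "patientid", list(
    element_mapping("Patient.gender", "value", source_column = "gender"),
    element_mapping("Patient.gender", "fixed", fixed_literal = "male"))),
    patient_prof, table)
  expect_true("duplicate-target" %in% dup$code)

  expect_error(check_mapping(rm_nogender,
                             profiles[["http://example.org/fhir/StructureDefinition/SyntheticObservationProfile"]],
                             table),
               class = "precondition")
})

test_that("a conforming reference mapping raises zero issues", {
  synth <- small_pipeline()$synth
  profiles <- pkg_profiles()
  config <- pkg_mapping("a")
  for (rm in config$resource_mappings) {
    issues <- check_mapping(rm, find_profile(profiles, rm$resource_type,
                                             rm$profile_url),
                            synth$tables[[rm$source_table]])
    expect_false(any(issues$severity == "error"),
                 info = paste("mapping for", rm$source_table))
  }
})

test_that("check_mapping is monotone and reports no phantom paths", {
  profiles <- pkg_profiles()
  prof <- profiles[["http://example.org/fhir/StructureDefinition/SyntheticEncounterProfile"]]
  table <- df_source_table(
    data.frame(admissionid = "a1", patientid = "p1",
               admitdate = "2023-01-01", dischargedate = "2023-01-05"),
    "admissions")
  full <- pkg_mapping("a")$resource_mappings[[2]]$element_mappings

  # adding one mapping at a time: missing-required errors only ever shrink
  prev_missing <- NULL
  for (k in 0:length(full)) {
    rm <- resource_mapping("admissions", "Encounter", "admissionid",
                           full[seq_len(k)])
    issues <- check_mapping(rm, prof, table)
    missing <- sort(issues$target_path[issues$code == "missing-required"])
    if (!is.null(prev_missing)) {
      expect_true(all(missing %in% prev_missing))
    }
    prev_missing <- missing
    # every issue's path exists in the profile or among the mapped targets
    mapped <- vapply(rm$element_mappings, `[[`, "", "target_path")
    for (p in issues$target_path) {
      expect_true(any(startsWith(p, prof$constraints$path)) || p %in% mapped)
    }
  }
  expect_length(prev_missing, 0)
})
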