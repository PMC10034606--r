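patient_profile <- function() {
  pkg_profiles()[["http://example.org/fhir/StructureDefinition/SyntheticPatientProfile"]]
}

conforming_patient <- function() {
  list(resourceType = "Patient", id = "abc123", gender = "female",
       birthDate = "1950-01-02")
}

test_that("a resource populating all required elements yields zero violations", {
  v <- validate_resource(conforming_patient(), patient_profile(),
                         pkg_valuesets())
  expect_identical(nrow(v), 0L)
})

test_that("missing required elements raise cardinality-min at the exact path", {
  p <- conforming_patient()
  p$gender <- NULL
  v <- validate_resource(p, patient_profile(), pkg_valuesets())
  # oracle: the required-path set difference is exactly {Patient.gender}
  expect_identical(v$code, "cardinality-min")
  expect_identical(v$path, "Patient.gender")
  expect_true(has_blocking_violation(v))
})

test_that("required bindings are enforced via value-set membership", {
  p <- conforming_patient()
  p$gender <- "W"
  v <- validate_resource(p, patient_profile(), pkg_valuesets())
  expect_identical(v$code, "binding")
  expect_identical(v$severity, "error")

  # oracle: linear membership scan of the ValueSet fixture
  vs <- pkg_valuesets()[["http://hl7.org/fhir/ValueSet/administrative-gender"]]
  expect_false("W" %in% vs)
  expect_true("female" %in% vs)

  # a coded Condition outside its (extensible) value set only warns
  cond_prof <- pkg_profiles()[["http://example.org/fhir/StructureDefinition/SyntheticConditionProfile"]]
  cond <- list(resourceType = "Condition", id = "c1",
               code = list(coding = list(list(
                 system = "http://hl7.org/fhir/sid/icd-10", code = "J44.0"))),
               subject = list(reference = "Patient/abc123"))
  vs2 <- list("http://example.org/fhir/ValueSet/icd-10-subset" = c("I10"))
  v2 <- validate_resource(cond, cond_prof, vs2)
  expect_identical(v2$code, "binding")
  expect_identical(v2$severity, "warning")
  expect_false(has_blocking_violation(v2))
})

test_that("a required binding against an unloaded value set degrades to a warning", {
  p <- conforming_patient()
  v <- validate_resource(p, patient_profile(), valuesets = list())
  expect_true(all(v$severity == "warning"))
  expect_false(has_blocking_violation(v))
})

test_that("primitive and complex datatype values are type-checked", {
  obs_prof <- pkg_profiles()[["http://example.org/fhir/StructureDefinition/SyntheticObservationProfile"]]
  obs <- list(resourceType = "Observation", id = "o1", status = "final",
              code = list(coding = list(list(system = "http://loinc.org",
                                             code = "718-7"))),
              subject = list(reference = "Patient/abc123"),
              valueQuantity = list(value = "not-a-number", unit = "g/L"))
  v <- validate_resource(obs, obs_prof, pkg_valuesets())
  expect_true("wrong-type" %in% v$code)
  expect_identical(v$path[v$code == "wrong-type"],
                   "Observation.valueQuantity.value")

  obs$valueQuantity$value <- 142
  expect_identical(nrow(validate_resource(obs, obs_prof, pkg_valuesets())), 0L)

  bad_date <- conforming_patient()
  bad_date$birthDate <- "02/01/1950"
  v2 <- validate_resource(bad_date, patient_profile(), pkg_valuesets())
  expect_true("wrong-type" %in% v2$code)
})

test_that("cardinality-max and fixed values are enforced", {
  doc <- tiny_patient_profile_doc(gender_min = 0L)
  doc$snapshot$element[[2]]$fixed <- NULL
  doc$snapshot$element[[2]]$fixedCode <- "female"
  prof <- build_constraint_tree(doc)

  p <- list(resourceType = "Patient", id = "x", gender = "male")
  v <- validate_resource(p, prof, pkg_valuesets())
  expect_true("fixed-mismatch" %in% v$code)

  p2 <- list(resourceType = "Patient", id = "x",
             gender = list("female", "female"))
  v2 <- validate_resource(p2, prof, pkg_valuesets())
  expect_true("cardinality-max" %in% v2$code)
})

test_that("the engine and validator agree on the all-valid synthetic corpus", {
  pipe <- small_pipeline()
  config <- pkg_mapping("a")
  profiles <- pipe$profiles
  idx <- pkg_index()
  vs <- pkg_valuesets()
  for (rm in config$resource_mappings) {
    table <- pipe$synth$tables[[rm$source_table]]
    prof <- find_profile(profiles, rm$resource_type, rm$profile_url)
    for (i in seq_len(nrow(table))) {
      res <- transform_row(rm, table[i, , drop = FALSE], prof, idx)
      v <- validate_resource(res, prof, vs)
      expect_false(has_blocking_violation(v),
                   info = sprintf("%s row %d", rm$source_table, i))
    }
  }
})

test_that("removing any populated required element breaks conformance", {
  pipe <- small_pipeline()
  profiles <- pipe$profiles
  config <- pkg_mapping("a")
  idx <- pkg_index()
  vs <- pkg_valuesets()
  for (rm in config$resource_mappings) {
    prof <- find_profile(profiles, rm$resource_type, rm$profile_url)
    res <- transform_row(rm, pipe$synth$tables[[rm$source_table]][1, , drop = FALSE],
                         prof, idx)
    for (req in required_paths(prof)) {
      top <- strsplit(sub(paste0("^", prof$resource_type, "\\."), "", req),
                      ".", fixed = TRUE)[[1]][1]
      mutated <- res
      mutated[[top]] <- NULL
      v <- validate_resource(mutated, prof, vs)
      expect_true(has_blocking_violation(v),
                  info = sprintf("%s without %s", rm$resource_type, req))
    }
  }
})
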