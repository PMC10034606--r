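{
  "version": "1.0",
  "fhir_endpoint": "embedded",
  "resource_mappings": [
    {
      "source_table": "subjects",
      "resource_type": "Patient",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile",
      "id_columns": ["subject_ref"],
      "element_mappings": [
        {"target_path": "Patient.gender", "kind": "value", "source_column": "sex_code",
         "translation": {"source_system": "http://example.org/fhir/CodeSystem/local-gender-b",
                         "target_system": "http://hl7.org/fhir/administrative-gender"}},
        {"target_path": "Patient.birthDate", "kind": "value", "source_column": "dob"}
      ]
    },
    {
      "source_table": "stays",
      "resource_type": "Encounter",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticEncounterProfile",
      "id_columns": ["stay_id"],
      "element_mappings": [
        {"target_path": "Encounter.status", "kind": "fixed", "fixed_literal": "finished"},
        {"target_path": "Encounter.class", "kind": "fixed",
         "fixed_literal": {"system": "http://terminology.hl7.org/CodeSystem/v3-ActCode", "code": "IMP"}},
        {"target_path": "Encounter.subject", "kind": "reference",
         "source_column": "subject_ref", "reference_target": "Patient"},
        {"target_path": "Encounter.period.start", "kind": "value", "source_column": "entry_date"},
        {"target_path": "Encounter.period.end", "kind": "value", "source_column": "exit_date"}
      ]
    },
    {
      "source_table": "labs",
      "resource_type": "Observation",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticObservationProfile",
      "id_columns": ["lab_id"],
      "element_mappings": [
        {"target_path": "Observation.status", "kind": "fixed", "fixed_literal": "final"},
        {"target_path": "Observation.code", "kind": "value", "source_column": "test_loinc",
         "translation": {"source_system": "http://loinc.org", "target_system": "http://loinc.org"}},
        {"target_path": "Observation.subject", "kind": "reference",
         "source_column": "subject_ref", "reference_target": "Patient"},
        {"target_path": "Observation.encounter", "kind": "reference",
         "source_column": "stay_id", "reference_target": "Encounter"},
        {"target_path": "Observation.valueQuantity.value", "kind": "value", "source_column": "result"},
        {"target_path": "Observation.valueQuantity.unit", "kind": "value", "source_column": "result_unit"},
        {"target_path": "Observation.effectiveDateTime", "kind": "value", "source_column": "test_date"}
      ]
    },
    {
      "source_table": "diagnoses",
      "resource_type": "Condition",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticConditionProfile",
      "id_columns": ["dx_id"],
      "element_mappings": [
        {"target_path": "Condition.code", "kind": "value", "source_column": "dx_icd10",
         "translation": {"source_system": "http://hl7.org/fhir/sid/icd-10", "target_system": "http://hl7.org/fhir/sid/icd-10"}},
        {"target_path": "Condition.subject", "kind": "reference",
         "source_column": "subject_ref", "reference_target": "Patient"},
        {"target_path": "Condition.onsetDateTime", "kind": "value", "source_column": "dx_date"}
      ]
    },
    {
      "source_table": "medications",
      "resource_type": "MedicationStatement",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticMedicationStatementProfile",
      "id_columns": ["med_id"],
      "element_mappings": [
        {"target_path": "MedicationStatement.status", "kind": "fixed", "fixed_literal": "active"},
        {"target_path": "MedicationStatement.medicationCodeableConcept", "kind": "value", "source_column": "atc_code",
         "translation": {"source_system": "http://www.whocc.no/atc", "target_system": "http://www.whocc.no/atc"}},
        {"target_path": "MedicationStatement.subject", "kind": "reference",
         "source_column": "subject_ref", "reference_target": "Patient"},
        {"target_path": "MedicationStatement.effectiveDateTime", "kind": "value", "source_column": "issued"}
      ]
    }
  ]
}
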