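{
  "version": "1.0",
  "fhir_endpoint": "embedded",
  "resource_mappings": [
    {
      "source_table": "patients",
      "resource_type": "Patient",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile",
      "id_columns": ["patientid"],
      "element_mappings": [
        {"target_path": "Patient.gender", "kind": "value", "source_column": "gender",
         "translation": {"source_system": "http://example.org/fhir/CodeSystem/local-gender-a",
                         "target_system": "http://hl7.org/fhir/administrative-gender"}},
        {"target_path": "Patient.birthDate", "kind": "value", "source_column": "birthdate"}
      ]
    },
    {
      "source_table": "admissions",
      "resource_type": "Encounter",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticEncounterProfile",
      "id_columns": ["admissionid"],
      "element_mappings": [
        {"target_path": "Encounter.status", "kind": "fixed", "fixed_literal": "finished"},
        {"target_path": "Encounter.class", "kind": "fixed",
         "fixed_literal": {"system": "http://terminology.hl7.org/CodeSystem/v3-ActCode", "code": "IMP"}},
        {"target_path": "Encounter.subject", "kind": "reference",
         "source_column": "patientid", "reference_target": "Patient"},
        {"target_path": "Encounter.period.start", "kind": "value", "source_column": "admitdate"},
        {"target_path": "Encounter.period.end", "kind": "value", "source_column": "dischargedate"}
      ]
    },
    {
      "source_table": "observations",
      "resource_type": "Observation",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticObservationProfile",
      "id_columns": ["obsid"],
      "element_mappings": [
        {"target_path": "Observation.status", "kind": "fixed", "fixed_literal": "final"},
        {"target_path": "Observation.code", "kind": "value", "source_column": "loinccode",
         "translation": {"source_system": "http://loinc.org", "target_system": "http://loinc.org"}},
        {"target_path": "Observation.subject", "kind": "reference",
         "source_column": "patientid", "reference_target": "Patient"},
        {"target_path": "Observation.encounter", "kind": "reference",
         "source_column": "admissionid", "reference_target": "Encounter"},
        {"target_path": "Observation.valueQuantity.value", "kind": "value", "source_column": "value"},
        {"target_path": "Observation.valueQuantity.unit", "kind": "value", "source_column": "unit"},
        {"target_path": "Observation.effectiveDateTime", "kind": "value", "source_column": "obsdate"}
      ]
    },
    {
      "source_table": "conditions",
      "resource_type": "Condition",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticConditionProfile",
      "id_columns": ["condid"],
      "element_mappings": [
        {"target_path": "Condition.code", "kind": "value", "source_column": "icd10code",
         "translation": {"source_system": "http://hl7.org/fhir/sid/icd-10", "target_system": "http://hl7.org/fhir/sid/icd-10"}},
        {"target_path": "Condition.subject", "kind": "reference",
         "source_column": "patientid", "reference_target": "Patient"},
        {"target_path": "Condition.onsetDateTime", "kind": "value", "source_column": "onsetdate"}
      ]
    },
    {
      "source_table": "prescriptions",
      "resource_type": "MedicationStatement",
      "profile_url": "http://example.org/fhir/StructureDefinition/SyntheticMedicationStatementProfile",
      "id_columns": ["rxid"],
      "element_mappings": [
        {"target_path": "MedicationStatement.status", "kind": "fixed", "fixed_literal": "active"},
        {"target_path": "MedicationStatement.medicationCodeableConcept", "kind": "value", "source_column": "medcode",
         "translation": {"source_system": "http://www.whocc.no/atc", "target_system": "http://www.whocc.no/atc"}},
        {"target_path": "MedicationStatement.subject", "kind": "reference",
         "source_column": "patientid", "reference_target": "Patient"},
        {"target_path": "MedicationStatement.effectiveDateTime", "kind": "value", "source_column": "startdate"}
      ]
    }
  ]
}
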