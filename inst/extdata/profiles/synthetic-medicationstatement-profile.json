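{
  "resourceType": "StructureDefinition",
  "id": "synthetic-medicationstatement-profile",
  "url": "http://example.org/fhir/StructureDefinition/SyntheticMedicationStatementProfile",
  "name": "SyntheticMedicationStatementProfile",
  "status": "active",
  "description": "Synthetic demonstration profile: prescription MedicationStatement with mandatory status, ATC-coded medication and subject.",
  "fhirVersion": "4.0.1",
  "kind": "resource",
  "abstract": false,
  "type": "MedicationStatement",
  "baseDefinition": "http://hl7.org/fhir/StructureDefinition/MedicationStatement",
  "derivation": "constraint",
  "snapshot": {
    "element": [
      {"path": "MedicationStatement", "min": 0, "max": "*"},
      {"path": "MedicationStatement.id", "min": 0, "max": "1", "type": [{"code": "id"}]},
      {"path": "MedicationStatement.meta", "min": 0, "max": "1", "type": [{"code": "Meta"}]},
      {"path": "MedicationStatement.status", "min": 1, "max": "1", "type": [{"code": "code"}],
       "binding": {"strength": "required", "valueSet": "http://hl7.org/fhir/ValueSet/medication-statement-status"}},
      {"path": "MedicationStatement.medication[x]", "min": 1, "max": "1", "type": [{"code": "CodeableConcept"}]},
      {"path": "MedicationStatement.subject", "min": 1, "max": "1",
       "type": [{"code": "Reference", "targetProfile": ["http://hl7.org/fhir/StructureDefinition/Patient"]}]},
      {"path": "MedicationStatement.effective[x]", "min": 0, "max": "1", "type": [{"code": "dateTime"}]}
    ]
  }
}
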