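{
  "resourceType": "StructureDefinition",
  "id": "synthetic-patient-profile",
  "url": "http://example.org/fhir/StructureDefinition/SyntheticPatientProfile",
  "name": "SyntheticPatientProfile",
  "status": "active",
  "description": "Synthetic demonstration profile: Patient with mandatory administrative gender.",
  "fhirVersion": "4.0.1",
  "kind": "resource",
  "abstract": false,
  "type": "Patient",
  "baseDefinition": "http://hl7.org/fhir/StructureDefinition/Patient",
  "derivation": "constraint",
  "snapshot": {
    "element": [
      {"path": "Patient", "min": 0, "max": "*"},
      {"path": "Patient.id", "min": 0, "max": "1", "type": [{"code": "id"}]},
      {"path": "Patient.meta", "min": 0, "max": "1", "type": [{"code": "Meta"}]},
      {"path": "Patient.identifier", "min": 0, "max": "*", "type": [{"code": "Identifier"}]},
      {"path": "Patient.gender", "min": 1, "max": "1", "type": [{"code": "code"}],
       "binding": {"strength": "required", "valueSet": "http://hl7.org/fhir/ValueSet/administrative-gender"}},
      {"path": "Patient.birthDate", "min": 0, "max": "1", "type": [{"code": "date"}]}
    ]
  }
}
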