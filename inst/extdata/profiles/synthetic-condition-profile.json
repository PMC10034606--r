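{
  "resourceType": "StructureDefinition",
  "id": "synthetic-condition-profile",
  "url": "http://example.org/fhir/StructureDefinition/SyntheticConditionProfile",
  "name": "SyntheticConditionProfile",
  "status": "active",
  "description": "Synthetic demonstration profile: diagnosis Condition with mandatory ICD-10-coded code and subject.",
  "fhirVersion": "4.0.1",
  "kind": "resource",
  "abstract": false,
  "type": "Condition",
  "baseDefinition": "http://hl7.org/fhir/StructureDefinition/Condition",
  "derivation": "constraint",
  "snapshot": {
    "element": [
      {"path": "Condition", "min": 0, "max": "*"},
      {"path": "Condition.id", "min": 0, "max": "1", "type": [{"code": "id"}]},
      {"path": "Condition.meta", "min": 0, "max": "1", "type": [{"code": "Meta"}]},
      {"path": "Condition.code", "min": 1, "max": "1", "type": [{"code": "CodeableConcept"}],
       "binding": {"strength": "extensible", "valueSet": "http://example.org/fhir/ValueSet/icd-10-subset"}},
      {"path": "Condition.subject", "min": 1, "max": "1",
       "type": [{"code": "Reference", "targetProfile": ["http://hl7.org/fhir/StructureDefinition/Patient"]}]},
      {"path": "Condition.onset[x]", "min": 0, "max": "1", "type": [{"code": "dateTime"}]}
    ]
  }
}
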