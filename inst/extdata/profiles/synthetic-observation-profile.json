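{
  "resourceType": "StructureDefinition",
  "id": "synthetic-observation-profile",
  "url": "http://example.org/fhir/StructureDefinition/SyntheticObservationProfile",
  "name": "SyntheticObservationProfile",
  "status": "active",
  "description": "Synthetic demonstration profile: laboratory Observation with mandatory status, LOINC code and subject; choice-typed value restricted to Quantity or CodeableConcept.",
  "fhirVersion": "4.0.1",
  "kind": "resource",
  "abstract": false,
  "type": "Observation",
  "baseDefinition": "http://hl7.org/fhir/StructureDefinition/Observation",
  "derivation": "constraint",
  "snapshot": {
    "element": [
      {"path": "Observation", "min": 0, "max": "*"},
      {"path": "Observation.id", "min": 0, "max": "1", "type": [{"code": "id"}]},
      {"path": "Observation.meta", "min": 0, "max": "1", "type": [{"code": "Meta"}]},
      {"path": "Observation.status", "min": 1, "max": "1", "type": [{"code": "code"}],
       "binding": {"strength": "required", "valueSet": "http://hl7.org/fhir/ValueSet/observation-status"}},
      {"path": "Observation.code", "min": 1, "max": "1", "type": [{"code": "CodeableConcept"}]},
      {"path": "Observation.subject", "min": 1, "max": "1",
       "type": [{"code": "Reference", "targetProfile": ["http://hl7.org/fhir/StructureDefinition/Patient"]}]},
      {"path": "Observation.encounter", "min": 0, "max": "1",
       "type": [{"code": "Reference", "targetProfile": ["http://hl7.org/fhir/StructureDefinition/Encounter"]}]},
      {"path": "Observation.effective[x]", "min": 0, "max": "1", "type": [{"code": "dateTime"}]},
      {"path": "Observation.value[x]", "min": 0, "max": "1",
       "type": [{"code": "Quantity"}, {"code": "CodeableConcept"}]}
    ]
  }
}
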