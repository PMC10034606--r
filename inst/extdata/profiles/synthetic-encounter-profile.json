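{
  "resourceType": "StructureDefinition",
  "id": "synthetic-encounter-profile",
  "url": "http://example.org/fhir/StructureDefinition/SyntheticEncounterProfile",
  "name": "SyntheticEncounterProfile",
  "status": "active",
  "description": "Synthetic demonstration profile: hospital admission Encounter with mandatory status, class, subject and admission period.",
  "fhirVersion": "4.0.1",
  "kind": "resource",
  "abstract": false,
  "type": "Encounter",
  "baseDefinition": "http://hl7.org/fhir/StructureDefinition/Encounter",
  "derivation": "constraint",
  "snapshot": {
    "element": [
      {"path": "Encounter", "min": 0, "max": "*"},
      {"path": "Encounter.id", "min": 0, "max": "1", "type": [{"code": "id"}]},
      {"path": "Encounter.meta", "min": 0, "max": "1", "type": [{"code": "Meta"}]},
      {"path": "Encounter.status", "min": 1, "max": "1", "type": [{"code": "code"}],
       "binding": {"strength": "required", "valueSet": "http://hl7.org/fhir/ValueSet/encounter-status"}},
      {"path": "Encounter.class", "min": 1, "max": "1", "type": [{"code": "Coding"}]},
      {"path": "Encounter.subject", "min": 1, "max": "1",
       "type": [{"code": "Reference", "targetProfile": ["http://hl7.org/fhir/StructureDefinition/Patient"]}]},
      {"path": "Encounter.period", "min": 1, "max": "1", "type": [{"code": "Period"}]},
      {"path": "Encounter.period.start", "min": 1, "max": "1", "type": [{"code": "dateTime"}]},
      {"path": "Encounter.period.end", "min": 0, "max": "1", "type": [{"code": "dateTime"}]}
    ]
  }
}
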