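{
  "resourceType": "ValueSet",
  "id": "medication-statement-status",
  "url": "http://hl7.org/fhir/ValueSet/medication-statement-status",
  "name": "MedicationStatementStatus",
  "status": "active",
  "compose": {
    "include": [
      {
        "system": "http://hl7.org/fhir/CodeSystem/medication-statement-status",
        "concept": [
          {"code": "active"}, {"code": "completed"}, {"code": "entered-in-error"},
          {"code": "intended"}, {"code": "stopped"}, {"code": "on-hold"},
          {"code": "unknown"}, {"code": "not-taken"}
        ]
      }
    ]
  }
}
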