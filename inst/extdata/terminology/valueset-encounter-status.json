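{
  "resourceType": "ValueSet",
  "id": "encounter-status",
  "url": "http://hl7.org/fhir/ValueSet/encounter-status",
  "name": "EncounterStatus",
  "status": "active",
  "compose": {
    "include": [
      {
        "system": "http://hl7.org/fhir/encounter-status",
        "concept": [
          {"code": "planned"}, {"code": "arrived"}, {"code": "triaged"},
          {"code": "in-progress"}, {"code": "onleave"}, {"code": "finished"},
          {"code": "cancelled"}
        ]
      }
    ]
  }
}
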