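{
  "resourceType": "ValueSet",
  "id": "observation-status",
  "url": "http://hl7.org/fhir/ValueSet/observation-status",
  "name": "ObservationStatus",
  "status": "active",
  "compose": {
    "include": [
      {
        "system": "http://hl7.org/fhir/observation-status",
        "concept": [
          {"code": "registered"}, {"code": "preliminary"}, {"code": "final"},
          {"code": "amended"}, {"code": "corrected"}, {"code": "cancelled"}
        ]
      }
    ]
  }
}
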