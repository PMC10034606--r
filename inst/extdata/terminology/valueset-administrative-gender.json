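{
  "resourceType": "ValueSet",
  "id": "administrative-gender",
  "url": "http://hl7.org/fhir/ValueSet/administrative-gender",
  "name": "AdministrativeGender",
  "status": "active",
  "compose": {
    "include": [
      {
        "system": "http://hl7.org/fhir/administrative-gender",
        "concept": [
          {"code": "male", "display": "Male"},
          {"code": "female", "display": "Female"},
          {"code": "other", "display": "Other"},
          {"code": "unknown", "display": "Unknown"}
        ]
      }
    ]
  }
}
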