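{
  "resourceType": "ConceptMap",
  "id": "local-gender-to-administrative-gender",
  "url": "http://example.org/fhir/ConceptMap/local-gender-to-administrative-gender",
  "name": "LocalGenderToAdministrativeGender",
  "status": "active",
  "description": "Synthetic stand-in for institutional gender code mappings: hospital-style H/M codes and registry-style 1/2 codes to HL7 administrative gender.",
  "group": [
    {
      "source": "http://example.org/fhir/CodeSystem/local-gender-a",
      "target": "http://hl7.org/fhir/administrative-gender",
      "element": [
        {"code": "H", "target": [{"code": "male", "equivalence": "equivalent"}]},
        {"code": "M", "target": [{"code": "female", "equivalence": "equivalent"}]},
        {"code": "U", "target": [{"code": "unknown", "equivalence": "wider"}]}
      ]
    },
    {
      "source": "http://example.org/fhir/CodeSystem/local-gender-b",
      "target": "http://hl7.org/fhir/administrative-gender",
      "element": [
        {"code": "1", "target": [{"code": "male", "equivalence": "equivalent"}]},
        {"code": "2", "target": [{"code": "female", "equivalence": "equivalent"}]},
        {"code": "0", "target": [{"code": "unknown", "equivalence": "wider"}]}
      ]
    }
  ]
}
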