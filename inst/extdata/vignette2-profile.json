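{
  "id": "case-vignette-2",
  "demographics": {
    "age": 89,
    "sex": "female",
    "living_situation": "living alone"
  },
  "diagnoses": [
    "idiopathic gout", "hyperuricemia", "osteoporosis",
    "varices on the lower limbs", "spondylosis", "scoliosis",
    "thyroid nodules", "gastro-oesophageal reflux disease", "hypertension",
    "hypercholesterolemia", "multi-nodular goiter", "senility",
    "presbycusis", "vertigo", "fatty liver"
  ],
  "medications": [
    "Allopurinol", "Pantoprazole", "Torasemide", "Ramipril",
    "Ibandronic acid", "Biotin", "Calcium+vitamin D3"
  ],
  "assessments": [
    { "instrument": "TUG", "score": 25 },
    { "instrument": "MMSE", "score": 25 },
    { "instrument": "CLOCK", "score": 3 }
  ],
  "limitations": [
    { "code": "b230", "qualifier": 2 }
  ]
}
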