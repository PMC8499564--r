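{
  "id": "case-vignette-1",
  "demographics": {
    "age": 81,
    "sex": "male",
    "living_situation": "married"
  },
  "diagnoses": [
    "hypertension",
    "type 2 diabetes mellitus with renal complications",
    "obesity",
    "aneurysm of the aorta abdominalis",
    "cardiomyopathy",
    "ischemic heart disease",
    "atrial fibrillation and atrial flutter",
    "long-term therapy with anticoagulants",
    "pulmonary emphysema",
    "chronic disorder of the lower pulmonary passages",
    "renal insufficiency"
  ],
  "medications": [
    "Losartan", "Colecalciferol", "Xipamid", "Phenprocoumon", "Torasemid",
    "Tamsulosin", "Ezetimib", "Allopurinol", "Bisoprolol", "Pantoprazol"
  ],
  "assessments": [
    { "instrument": "TUG", "score": 14 },
    { "instrument": "GDS", "score": 7 },
    { "instrument": "IADL", "item": "shopping", "score": 0 },
    { "instrument": "IADL", "item": "housekeeping", "score": 0 }
  ],
  "limitations": [
    { "code": "b280", "qualifier": 1 }
  ]
}
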