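{
  "primary_disease": [
    "Disease progression",
    "Malignant neoplasm progression",
    "Breast cancer",
    "Breast cancer metastatic",
    "Neoplasm malignant"
  ],
  "disease_outcome": [
    "Death",
    "Disease recurrence",
    "Cardiac death"
  ],
  "non_reference": [
    "Investigation",
    "Off label use",
    "Product use issue",
    "Drug ineffective"
  ],
  "unspecified": [
    "Oncologic complication",
    "Adverse event",
    "Adverse drug reaction",
    "Therapeutic response unexpected"
  ]
}
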