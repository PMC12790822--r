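[
  {
    "extId": "PMC:1234567",
    "pmcid": "PMC1234567",
    "annotations": [
      {"prefix": "that ", "exact": "PTEN", "postfix": " is a direct", "type": "Gene_Proteins"},
      {"prefix": "with ", "exact": "SMAD4", "postfix": " signalling", "type": "Gene_Proteins"},
      {"prefix": "of ", "exact": "PTEN", "postfix": " protein", "type": "Gene_Proteins"}
    ]
  }
]
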