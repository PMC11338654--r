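[
  { "label_asym_id": "A", "component": "Protein" },
  { "label_asym_id": "B", "component": "Protein" },
  { "label_asym_id": "C", "component": "DNA" },
  { "label_asym_id": "D", "component": "DNA" },
  { "label_asym_id": "E", "component": "Gold" },
  { "label_asym_id": "H", "component": "Gold" },
  { "label_asym_id": "F", "component": "Chloride" },
  { "label_asym_id": "G", "component": "Chloride" },
  { "label_asym_id": "I", "component": "Chloride" }
]
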