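[
  -0.3965220392, 0.9180228028, 0.0020990366, 0,
  0.9068461183, 0.3913367028, 0.1564790811, 0,
  0.1428299346, 0.0639509075, -0.9876790426, 0,
  -17.6360858967, 7.9707613147, 88.5461324803, 1
]
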