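{
  "n_subjects": 4,
  "n_specific": 68,
  "n_cross_reactive": 11,
  "n_public": 1,
  "per_antigen": {
    "G12A": 12,
    "G12C": 14,
    "G12D": 11,
    "G12R": 15,
    "G12V": 14,
    "G13D": 13
  },
  "reference_condition": "vehicle_only"
}
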