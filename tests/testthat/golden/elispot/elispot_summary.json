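{
  "n_evaluable": 4,
  "n_responders_pooled": 3,
  "n_responders_tumor_matched": 4,
  "positivity_histogram": {
    "0": 0,
    "1": 1,
    "2": 0,
    "3": 1,
    "4": 1,
    "5": 0,
    "6": 1
  },
  "logrank_p": 1,
  "k": 2.77,
  "window_weeks": 17,
  "scale": "sfu"
}
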