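{
  "model": "phase3",
  "scenario": "stored in SGF pH 2 for 20 min before pepsin addition",
  "unit": "pL",
  "V0": 197.4,
  "pulse3": {"n": 0.0141, "t_plus": 193.5, "sigma": 37},
  "V4": 122.3,
  "t4": 141.7,
  "V_inf": 55.5,
  "breakpoint": 147,
  "fixed": ["sigma3"]
}
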