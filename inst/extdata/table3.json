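{
  "model": "system",
  "scenario": "SGF pH 2 + pepsin, stock-and-flow simulator",
  "unit": "fL",
  "V0": 217.45,
  "gauss1": {"n": 0.000423, "t_plus": 187.5, "sigma": 11},
  "gauss2": {"n": 0.00017, "t_plus": 300, "sigma": 35.15},
  "gauss3": {"n": 0.0141, "t_plus": 510, "sigma": 37.16},
  "RC1": 0.0032,
  "nx": 1.5,
  "RC2": 0.005,
  "RC3": 0.1533,
  "t_pulse1_start": 300,
  "t_pH28": 424,
  "Degt": 536,
  "dt": 0.25,
  "t_end": 2400
}
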