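{
  "acquisition": {"te_ms": 35, "tr_ms": 2000},
  "water_relaxation": {
    "gm": {"t1_s": 1.331, "t2_s": 0.11},
    "wm": {"t1_s": 0.832, "t2_s": 0.0799},
    "csf": {"t1_s": 4.163, "t2_s": 0.503}
  },
  "metabolite_relaxation": {
    "tCr": {"t1_s": 1.35, "t2_s": 0.166}
  },
  "densities": {"gm": 0.78, "wm": 0.65, "csf": 0.97},
  "h2o_molar": 55.51
}
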