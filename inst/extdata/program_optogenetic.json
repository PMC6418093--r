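{
  "total_s": 540,
  "epochs": [
    {"label": "baseline", "start_s": 0, "end_s": 120},
    {"label": "stimulus", "start_s": 120, "end_s": 420,
     "pulse": {"hz": 40, "width_ms": 25}},
    {"label": "recovery", "start_s": 420, "end_s": 540}
  ]
}
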