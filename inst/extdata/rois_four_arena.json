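{
  "frame": [640, 480],
  "rois": [
    {"label": "arena1", "center": [160, 120], "radius": 110},
    {"label": "arena2", "center": [480, 120], "radius": 110},
    {"label": "arena3", "center": [160, 360], "radius": 110},
    {"label": "arena4", "center": [480, 360], "radius": 110}
  ]
}
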