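{
  "width": {"value": 500, "unit": "um"},
  "height": {"value": 220, "unit": "um"},
  "spiral_radius": {"value": 5, "unit": "mm"},
  "n_loops": 10,
  "loop_spacing": {"value": 300, "unit": "um"},
  "n_outlets": 5,
  "outlet_width": {"value": 100, "unit": "um"},
  "fluid": {
    "density": {"value": 1, "unit": "g/ml"},
    "viscosity": {"value": 1, "unit": "mPa.s"}
  }
}
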