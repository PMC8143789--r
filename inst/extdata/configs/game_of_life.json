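{
  "grid": {
    "width": 50,
    "height": 50,
    "torus_x": true,
    "torus_y": true
  },
  "density": 0.5,
  "schedule": {
    "n_steps": 500,
    "png_every": 20
  }
}
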