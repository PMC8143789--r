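{
  "grid": {
    "torus_x": true,
    "torus_y": true,
    "width": 200,
    "height": 200
  },
  "kinds": [
    {
      "name": "dark"
    },
    {
      "name": "light"
    }
  ],
  "hamiltonian": {
    "temperature": 10,
    "J": [
      [0, 16, 16],
      [16, 6, 20],
      [16, 20, 6]
    ],
    "lambda_v": [2, 2],
    "target_v": [125, 125]
  },
  "processes": [
    {
      "type": "seed_circle",
      "counts": [50, 50],
      "kinds": [1, 2],
      "radius": 67,
      "burn_in": 50
    }
  ],
  "schedule": {
    "n_mcs": 2000,
    "log_every": 10,
    "png_every": 100
  },
  "outputs": {
    "draw_mode": "kind",
    "zoom": 1
  }
}
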