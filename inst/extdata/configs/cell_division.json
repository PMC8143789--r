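{
  "grid": {
    "torus_x": true,
    "torus_y": true,
    "width": 500,
    "height": 500
  },
  "kinds": [
    {
      "name": "cell"
    }
  ],
  "hamiltonian": {
    "temperature": 10,
    "J": [
      [0, 12],
      [12, 6]
    ],
    "lambda_v": 5,
    "target_v": 100
  },
  "processes": [
    {
      "type": "seed_circle",
      "counts": 20,
      "kinds": 1,
      "radius": 35,
      "burn_in": 30
    },
    {
      "type": "grow_divide",
      "growth_rate": 0.2,
      "division_volume": 180,
      "base_target_v": 100,
      "axis_mode": "minor-axis"
    }
  ],
  "schedule": {
    "n_mcs": 40000,
    "log_every": 100,
    "png_every": 1000
  },
  "outputs": {
    "draw_mode": "kind",
    "zoom": 1
  }
}
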