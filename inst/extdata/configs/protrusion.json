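{
  "grid": {
    "torus_x": true,
    "torus_y": true,
    "width": 200,
    "height": 200
  },
  "kinds": [
    {
      "name": "cell"
    },
    {
      "name": "obstacle"
    }
  ],
  "hamiltonian": {
    "temperature": 20,
    "J": [
      [0, 20, 20],
      [20, 0, 20],
      [20, 20, 0]
    ],
    "lambda_v": [50, 0],
    "target_v": [500, 0],
    "lambda_p": [2, 0],
    "target_p": [340, 0],
    "lambda_act": [200, 0],
    "max_act": [80, 0]
  },
  "processes": [
    {
      "type": "seed_circle",
      "counts": 1,
      "kinds": 1,
      "radius": 1,
      "burn_in": 30
    },
    {
      "type": "obstacles",
      "centers": [
        [50, 100],
        [150, 100]
      ],
      "radius": 10,
      "kind": 2
    }
  ],
  "schedule": {
    "n_mcs": 15000,
    "log_every": 10,
    "png_every": 250
  },
  "outputs": {
    "draw_mode": "kind",
    "zoom": 1
  }
}
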