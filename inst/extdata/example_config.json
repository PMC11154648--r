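{
  "seed": 42,
  "world": {
    "n_provinces": 12,
    "n_coastal": 5,
    "grid_cells_per_region": 3,
    "total_supply": 5000,
    "total_demand": 4200
  },
  "gravity": {
    "beta": 1,
    "estimate_beta": true,
    "noise_gsd": 1.1
  },
  "optimizer": {
    "w_cost": 0.5,
    "w_health": 0.5,
    "run_pareto": false
  }
}
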