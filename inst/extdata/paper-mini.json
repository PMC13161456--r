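{
  "experiment": "lung_spine",
  "grid_dim": [32, 32, 32],
  "voxel_mm": 9,
  "n_views": 24,
  "sphere_volumes_ml": [8, 16, 30],
  "noise_totals": {"eta_min": 400000, "eta_med": 120000, "eta_max": 40000},
  "n_realizations": 3,
  "n_iterations": 5,
  "n_subsets": 12,
  "base_seed": 1
}
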