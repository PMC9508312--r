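{
  "mode": "synthetic",
  "seed": 42,
  "cohort": {
    "n_patients": 15,
    "n_controls": 15,
    "attenuation": 0.3,
    "duration_s": 120,
    "fs": 120,
    "hdrs_model": null
  },
  "bandpass": null,
  "bands": {
    "alpha": [8, 13],
    "beta": [13, 30],
    "gamma": [30, 50]
  },
  "freq_grid": { "lo": 1, "hi": 45, "step": 0.5 },
  "mvar": { "order": 3, "max_order": 5 },
  "block_band": "alpha",
  "condition": "EC",
  "cor_scope": "all",
  "cor_metrics": ["C", "L", "LL", "RL"]
}
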