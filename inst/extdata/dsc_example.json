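{
  "te_s": 0.0345,
  "dt_s": 1.02,
  "n_t": 118,
  "rcbv_ratio": 0.65,
  "noise_sd": 10,
  "grid_dim": [16, 16, 1]
}
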