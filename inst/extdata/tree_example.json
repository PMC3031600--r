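{
  "domain_edge_mm": 1.0,
  "target_density": 25,
  "seg_length_mean_mm": 0.22,
  "seg_length_min_mm": 0.15,
  "angle_mean_deg": 50,
  "angle_sd_deg": 15
}
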