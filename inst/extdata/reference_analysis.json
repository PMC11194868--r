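{
  "description": "Marginals of the national 2021 census SA2-level childhood asthma analysis used as calibration anchors",
  "n_areas": 2321,
  "n_hotspot": 465,
  "n_coldspot": 548,
  "prevalence_mean_pct": 6.27,
  "prevalence_sd_pct": 1.95
}
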