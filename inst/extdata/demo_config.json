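{
  "synthetic": {
    "n_chroms": 6,
    "chrom_length": 5e7,
    "n_tumours": 60,
    "intercept": 1.7917595,
    "n_hotspots": 2,
    "hotspot_multiplier": 15
  },
  "gamma": 10,
  "kmin": 10,
  "n_reps": 50,
  "fdr": 0.05,
  "seed": 1,
  "out_dir": "demo_out"
}
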