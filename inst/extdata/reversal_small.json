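{
  "task": "reversal",
  "regime": "dual_estimation",
  "r": 0.1,
  "v": 0.85,
  "n_trials": 64,
  "replicates": 5,
  "windows": [1, 4, 16],
  "seed": 1,
  "n_boot": 200
}
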