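{
  "mode": "movie",
  "seed": 1,
  "out_dir": "demo_output",
  "movie": {
    "n_fusion": 5,
    "n_accumulation": 5,
    "n_loss": 3,
    "stimulus_duration": 0.5,
    "amp_sd": 8,
    "k_sd": 4,
    "window_s": 10
  }
}
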