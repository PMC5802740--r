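sigma0_sq: 0.25
method: p_interval
level: 0.8
reps: 2000.0
seed: 1.0
selection:
  mode: min_of_L
  L: 10000.0
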