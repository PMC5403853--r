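# Two-timescale synthetic benchmark, slow-first multirate coupling
engine:
  strategy: slow-first
  communication: asynchronous
  mode: multirate
  t_end: 2.0
  reltol: 1.0e-6
  abstol_factor: 1.0e-3
model:
  name: synthetic
  synthetic:
    stiffness_ratio: 1000
    coupling_strength: 0.5
    signal_speed: slow
sweep:
  tolerances: [1.0e-5, 1.0e-6, 1.0e-7]
  t_eval: 2.0
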