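# Electrical-chemical test case, slow exchanged signal (calcium
# concentration solved on the electrical side). Model parameters default
# to the package's documented values; override any of them here.
engine:
  strategy: fast-first
  communication: asynchronous
  mode: multirate
  t_end: 2.0
  reltol: 1.0e-5
  abstol_factor: 1.0e-3
model:
  name: TC-slow
  electrical: {}
  biochemical: {}
  protocol: {}
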