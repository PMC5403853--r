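# Electrical-chemical test case, fast exchanged signal (calcium flux
# communicated to the biochemical component, which owns the calcium pool).
engine:
  strategy: fast-first
  communication: asynchronous
  mode: multirate
  t_end: 2.0
  reltol: 1.0e-5
  abstol_factor: 1.0e-3
model:
  name: TC-fast
  electrical: {}
  biochemical: {}
  protocol: {}
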