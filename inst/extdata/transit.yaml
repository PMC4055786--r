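# Transit-compartment absorption chain: single 100 mg dose through 15
# transit compartments into plasma.
solver:
  method: rk4
  start_time: -1.0
  stop_time: 120.0
  dt: 0.02
model:
  id: transit
  params:
    n_transit: 15
    ktr: 0.25
    kout: 0.25
regimens:
- amount: 100.0
  first_time: 0.0
  interval: 24.0
  n_doses: 1
  target: transit1
seed: 1
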