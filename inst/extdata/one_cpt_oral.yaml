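# One-compartment oral PK: 100 mg daily for 3 doses.
solver:
  method: rk4
  start_time: -1.0
  stop_time: 100.0
  dt: 0.02
model:
  id: one_cpt_oral
  params:
    ka: 0.1
    ke: 0.1
    V1: 1.0
regimens:
- amount: 100.0
  first_time: 0.0
  interval: 24.0
  n_doses: 3
seed: 1
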