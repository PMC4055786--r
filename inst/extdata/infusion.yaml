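# 2 h zero-order infusion at 7 mg/h every 24 h into a one-compartment model.
solver:
  method: rk4
  start_time: -1.0
  stop_time: 100.0
  dt: 0.02
model:
  id: one_cpt_bolus
  params:
    ke: 1.0
regimens:
- route: infusion
  infusion_rate: 7.0
  infusion_duration: 2.0
  interval: 24.0
  target: central
seed: 1
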