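# Full-binding target-mediated drug disposition, monoclonal antibody in
# days: 150 mg subcutaneous every 28 days (amount converted to nmol via the
# 0.15 mass-concentration factor).
solver:
  method: adaptive_stiff
  start_time: -28.0
  stop_time: 84.0
  dt_min: 1.0e-3
  dt_max: 0.1
  tolerance: 1.0e-3
  dt_out: 0.5
model:
  id: tmdd
  params:
    kon: 1.0
    Kd: 1.5
    keD: 0.03
    keT: 0.5
    keTD: 0.1
    RateT: 50.0
    V: 7.0
    ka: 1.0
regimens:
- amount: 1000.0   # 150 mg / 0.15
  first_time: 0.0
  interval: 28.0
  target: S
seed: 1
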