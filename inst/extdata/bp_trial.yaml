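# Blood-pressure success trial: 100 patients, 150 mg daily for 4 doses,
# success = at least 20 mmHg reduction at 72 h (trough).
trial:
  kind: bp
  design:
    dose: 150.0
    n_doses: 4
    n_subjects: 100
    eval_time: 72.0
    pd_threshold: -20.0
seed: 1
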