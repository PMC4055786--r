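# Flare / randomized-withdrawal trial: 18 patients per arm treated from
# time 0, randomized at day 56 to continued treatment or withdrawal,
# weekly visits to day 224.
trial:
  kind: flare
  design:
    n_per_arm: 18
    tau: 56.0
    start_p2: 56.0
    start_time: -28.0
    stop_time: 224.0
    visit_freq: 7.0
seed: 1
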