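# Demonstration pipeline configuration: every stage on a small synthetic
# experiment. Runs end-to-end in a few minutes on one CPU.
seed: 20240301
stages:
  - synth
  - traits
  - geochip
  - stats
  - network
  - mend_sim
  - calibrate
  - warming_effects
synth:
  n_taxa: 120
  n_samples_per_group: 8
  depth: 8000
forcing:
  n_days: 365
probes:
  n_probes: 300
  detection_rate: 0.85
stats:
  permutations: 99
  null_reps: 100
network:
  min_prevalence: 5
  threshold: 0.6
calibrate:
  mode: gMEND
  max_evals: 150
  parameters: [Vd, Ec, mR, Vp2]
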