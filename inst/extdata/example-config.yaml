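# Example pipeline configuration: a small synthetic cohort generated from
# the two-prior belief-state model, fitted with two variants.
n_mice: 3
generating_model: bs_two_prior
schedule_config:
  include: probe
  n_days_probe: 4
weights_init: asymptotic
variants:
  - bs_two_prior
  - std_dual
n_starts: 5
mc_samples: 100000
seed: 1
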