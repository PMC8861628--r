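# Example pipeline configuration for `kgemr run --config example-config.yaml`
out_dir: kgemr_run
seed: 42
variants: [baseline, "+sm", "+sm∪"]
estimators: [lr]
protocol: screen
cohort:
  n_hospitalized: 714
  n_not_hospitalized: 732
  vocab_size_words: 300
  n_signal_concepts: 6
  n_noise_concepts: 40
  effect_sizes: [2, 2, 2, 2, 2, 2]
  abbreviation_rate: 0.2
fixture:
  n_signal_concepts: 6
  n_entities_per_signal: 6
  n_noise_concepts: 40
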