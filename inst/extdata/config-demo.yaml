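# Demo pipeline configuration: synthetic survey at the default study
# conditions, all stages enabled. Every random stage carries its own seed,
# so two runs of this config are byte-identical.
synthetic:
  S: 200
  specialist_fraction: 0.15
  pool_seed: 101
  survey_seed: 202
  plots_per_habitat: 2
  per_species_cap: 10
  per_plot_cap: 150
  casual_effort: 500
stages:
  checklist: true
  substrate: true
  assemblage: true
parameters:
  chao_variant: classic
  current_year: 2019
  extinction_horizon: 50
  band_threshold: 100
  min_systematic_records: 25
  nmds_starts: 10
  nmds_seed: 303
  mrpp_B: 999
  mrpp_seed: 404
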