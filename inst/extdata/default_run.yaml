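# Example run configuration for hfvoi (see ?run_config for every key).
# Scaled down from the full analysis defaults (2,500 PSA draws, EVPPI caps
# of 2,500/1,000) so a complete run finishes in minutes on one CPU.
analysis: ALL_NYHA
n_psa_draws: 500
lambda_max: 100000
lambda_step: 1000
evppi_step: 500
evppi_caps:
  TRANSITIONS: 1000
  UTILITIES: 500
  HOSP_ER: 500
  CONTACTS_COSTS: 500
  INITIAL_DIST: 500
evppi_lambdas: [0, 10000, 20000, 40000, 60000, 80000, 100000]
generator_config:
  effect_nts: 0.12
  effect_htm: 0.20
population:
  base: 160000
  increment: 5000
  years: 20
  start_year: 2018
  discount_rate: 0.04
  nyha4_fraction: 0.0732
seed: 1
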