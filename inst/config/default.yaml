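# Default run configuration for the ipm-demog pipeline.
simulate:
  preset: northwest-like
  n_years: 19
  seed: 1
fit:
  chains: 4
  iter: 20000
  burnin: 10000
  thin: 10
  seed: 1
  rho_prior: hierarchical
analyze:
  rates: [phi_ad, brood, phi_egg_period, phi_chick_period, fpba, rho]
surface:
  resolution: 50
  mode: expected
substitute:
  rate: productivity
  from_year: 2003
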