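# Example run configuration for run_pipeline(): a small synthetic seascape
# fitted end to end. Replace `simulate` with `inputs` paths (ASCII grids and
# CSVs) to run on survey data.
seed: 11
simulate:
  enabled: true
  nx: 60
  ny: 40
  cellsize: 25
  n_per_stratum: 4
  n_species: 5
  n_years: 2
radii: [500, 1000, 1500]
filter:
  fraction: 0.10
  mode: any
model:
  terms: [substratum, depth, boundary, diversity]
  n_factors: 2
  random: [site, year]
  diversity_radius: 500
priors:
  beta_var: 10000.0
  shape: 0.1
  rate: 0.1
mcmc:
  chains: 2
  iterations: 2000
  burnin: 800
  thin: 2
evaluate:
  cv_folds: 0
  select_radius: false
predict:
  enabled: true
  year: 2021
  max_draws: 100
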