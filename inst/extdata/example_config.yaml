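# Example simulation-mode pipeline configuration (synthetic data).
# Run: run_pipeline(system.file("extdata", "example_config.yaml",
#                               package = "commNmix"), out = "run1")
seed: 42
mode: simulate
design:
  n_sites: 6
  points_per_site: 5
  n_years: 1
  visits_per_year: 3
  suites:
    BAOR: Forested Upland
    WOTH: Forested Upland
    EATO: Scrub-Shrub
    PRAW: Scrub-Shrub
    FISP: Scrub-Shrub
    EAKI: Grassland
mcmc:
  n_chains: 2
  n_iter: 1000
  n_burnin: 400
  thin: 3
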