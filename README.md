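# commNmix

Hierarchical community N-mixture models with zero inflation for
repeated point-count data.

## The problem

Point counts of breeding birds undercount: a bird present in the plot
is detected only with some probability per visit, and raw counts
confound abundance with detectability. For a community of species
surveyed repeatedly — here the motivating case is priority upland
birds in managed vs unmanaged pine forest, with vegetation structure
(grass and woody groundcover, visual obstruction at 2 m, live-tree
basal area) measured at each point — the questions are: how does
abundance respond to forest structure at the community, habitat-suite
and species level, and which species co-occur where?

`commNmix` answers these with a Bayesian hierarchical N-mixture model.
For species *i*, point *j*, year *r*, visit *v*:

    a_ijr ~ Bernoulli(psi_i)                      # zero inflation
    M_ijr | a ~ Poisson(a_ijr * lambda_ijr)       # latent abundance
    log lambda_ijr = beta0_i + beta_i' x_jr + gamma_site
    y_ijrv ~ Binomial(M_ijr, phi_ijrv)            # per-visit counts
    logit phi_ijrv = alpha0_i + alpha_i' v_jrv

Species-level coefficients are drawn from community Normal
hyperdistributions (`beta0_i ~ N(mu_beta0, sigma_beta0^2)`, etc.), so
rare species borrow strength and the hyper-means are community-level
effects. The discrete latent states `(a, M)` are marginalized
**exactly** out of the likelihood; the posterior is sampled with an
adaptive Metropolis-within-Gibbs scheme (conjugate updates for
hyper-means), with Gelman–Rubin R-hat diagnostics and the 95%
credible-interval significance rule. Derived posteriors include
detection probability `P_d`, zero-inflation `psi`, presence–absence
z-matrices and pairwise Jaccard co-occurrence indices with full
uncertainty propagation. A survey simulator
(`simulate_community()`) generates datasets with exactly the model's
structure — 150 points in 18 half-treatment/half-control sites, 3
visits × 4 years, 12 species in 3 suites by default — for recovery
studies and testing.

## Worked example

Simulate one survey year at the reference design and fit:

```r
library(commNmix)
des <- survey_design(n_years = 1)          # 150 points, 18 sites, 3 visits
sim <- simulate_community(des, seed = 11)  # covariates, parameters, counts
fit <- comm_nmix(sim$counts, sim$covariates,
                 config = mcmc_config(n_chains = 2, n_iter = 2000,
                                      n_burnin = 800, thin = 3, seed = 5))
print(fit)
```

```
Hierarchical community N-mixture model (zero-inflated)
  12 species, 150 point-year cells, 3 visits; 18 site(s)
  2 chain(s) x 400 kept draws (55.1 s)

Community hyperparameters:
               parameter     mean          95% CrI  rhat sig
                mu_beta0    0.272  (-0.269, 0.783) 1.030
           mu_beta_grass    0.070  (-0.188, 0.309) 1.004
           mu_beta_woody   -0.164 (-0.316, -0.010) 0.999   *
            mu_beta_vor2   -0.141  (-0.296, 0.009) 1.001
           mu_beta_basal   -0.483 (-0.655, -0.271) 1.005   *
       mu_beta_treatment    0.230  (-0.351, 0.795) 1.003
               mu_alpha0   -1.550 (-2.004, -1.184) 1.049   *
           mu_alpha_date   -0.545 (-0.678, -0.410) 1.012   *
           ...
```

The generating hyper-means here were 0.4 (intercept), 0.05, −0.15,
−0.1, −0.4 (basal), 0.45 (treatment) and −1.5 (detection intercept).
In this single replicate 10 of the 11 hyper-mean CrIs cover their
generating values (the date effect narrowly misses, as a 95% interval
sometimes should — the replicated recovery study in the test suite
shows coverage at the nominal rate). The strong negative basal-area
effect is recovered with the right sign and flagged significant
(`*` = CrI excludes 0), and all R-hat values are below 1.1.

Derived quantities:

```r
detection_summary(fit)      # P_d by species / suite / community
```

```
   quantity     level            name      mean     lower     upper
13      P_d     suite Forested Upland 0.1824254 0.1319090 0.2278043
14      P_d     suite     Scrub-Shrub 0.1747705 0.1164031 0.2316150
15      P_d     suite       Grassland 0.2232223 0.1441971 0.3424608
16      P_d community       community 0.1826356 0.1348832 0.2265322
```

Community mean detection of ~0.18 per 10-min survey: a bird present in
the plot is counted less than one visit in five, which is exactly why
the latent-abundance correction matters.

```r
zm <- build_z_matrix(fit, n_draws = 400, seed = 2)
js <- jaccard_posterior(zm)          # 66 pairs for 12 species
head(js[order(-js$mean), ], 3)
```

```
   species_i species_j      mean     lower     upper n_dropped
16      BAOR      FISP 0.4415493 0.3593490 0.5307812         0
46      BAOR      SCTA 0.4241064 0.3491626 0.5040984         0
7       BAOR      EAKI 0.4171625 0.3587675 0.4867257         0
```

Each Jaccard index is the posterior share of occupied points the two
species share (0 = never together, 1 = always), with credible
intervals that propagate the abundance model's uncertainty.

A whole analysis (simulate or read data → standardize → collinearity
screen → treatment/control t-tests → fit → summaries → Jaccard) runs
from one configuration via `run_pipeline()`, writing delimited tables
plus a manifest stamped with the config hash.

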