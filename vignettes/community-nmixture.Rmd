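---
title: "Hierarchical community N-mixture models with zero inflation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical community N-mixture models with zero inflation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commNmix)
```

# The model

`commNmix` estimates abundance of a multi-species breeding-bird community
from repeated point counts while correcting for imperfect detection. The
motivating setting is a managed-forest study: survey points split between
actively managed (treatment) and unmanaged (control) stands, visited
several times per season, with vegetation structure measured at each
point (grass and woody groundcover, horizontal visual obstruction at 2 m
"VOR2", and live-tree basal area) and survey conditions recorded at each
visit (date, wind, ambient disturbance).

For species $i$, point $j$, year $r$ and visit $v$, the process model is
a zero-inflated Poisson N-mixture:

$$a_{ijr} \sim \mathrm{Bernoulli}(\psi_i), \qquad
  M_{ijr} \mid a \sim \mathrm{Poisson}(a_{ijr}\,\lambda_{ijr}),$$

$$\log \lambda_{ijr} = \beta_{0(i)} + \boldsymbol\beta_{(i)}'\mathbf{x}_{jr} + \gamma_{t(j)},$$

and the observation model is a binomial thinning per visit:

$$y_{ijrv} \sim \mathrm{Binomial}(M_{ijr}, \varphi_{ijrv}), \qquad
  \mathrm{logit}\,\varphi_{ijrv} = \alpha_{0(i)} + \boldsymbol\alpha_{(i)}'\mathbf{v}_{jrv}.$$

The inclusion indicator $a$ absorbs the excess structural zeros typical
of count data on patchily distributed species; $\gamma_t$ is a site
random effect shared across species, $N(0, \sigma_{\text{site}}^2)$.
Community structure enters through hyperdistributions: every
species-level coefficient is drawn from a Normal hyperprior, e.g.
$\beta_{0(i)} \sim N(\mu_{\beta_0}, \sigma_{\beta_0}^2)$, and likewise
for each abundance and detection slope. Rare species thereby borrow
strength from the community, and the hyper-means are the
community-level effects of management covariates. Neither year nor
observer enters the model: vegetation is the target of inference in a
space-for-time design, and observers turn over exactly with years, so
either term would confound the vegetation effects.

Detection $\varphi$ is a composite of presence, availability and
detectability; the model does not decompose it further, which assumes
occupancy and availability are effectively constant across visits
within a season.

## Priors

* Fixed-effect hyper-means: vague $N(0, \text{precision } 0.001)$
  (sd $\approx 31.6$).
* Hyper standard deviations and $\sigma_{\text{site}}$: half-Normal
  with scale 2 — weakly informative on the plausible range of
  among-species spread on the log/logit scale; the scale is
  configurable in `model_spec()`. These priors are a design choice of
  this package: only the fixed-effect priors are pinned down by the
  original analysis convention, so scale parameters get a standard
  weakly-informative default.
* Zero-inflation $\psi_i$: Beta(1, 1) per species, independent.

## Exact marginalization

Rather than sampling the discrete latent states $(a, M)$, the
likelihood of each species × point × year cell marginalizes them
exactly:

$$L = (1-\psi)\,\mathbf{1}\{\text{all } y = 0\}
  + \psi \sum_{M = \max(y)}^{K} \mathrm{Pois}(M;\lambda)
  \prod_v \mathrm{Binom}(y_v; M, \varphi_v).$$

The posterior of the continuous parameters is identical to the
latent-state formulation, but mixing is far better because the sampler
never has to move a discrete abundance. Latent states are recovered
afterwards from their conditional distribution where they are needed
(the presence–absence z-matrix).

**Truncation.** The infinite sum over $M$ is truncated adaptively: it
starts at $\max(y)$ and stops once terms are past their mode and each
further term contributes less than $10^{-3} \cdot \texttt{tail}$ of the
running sum (default `tail = 1e-12`, cap `Kcap = 300`). Because the
terms decay super-geometrically past the mode, the total truncation
error is a small multiple of that threshold — in practice the marginal
agrees with brute-force enumeration to better than $10^{-13}$, which is
what the test suite asserts (at $10^{-10}$). A forced fixed `K` is
available for cross-checks.

# Sampling

The posterior is explored with an adaptive Metropolis-within-Gibbs
scheme, written for this likelihood:

* species-level coefficients, logit-$\psi_i$ and site effects
  $\gamma_t$: scalar random-walk Metropolis with per-parameter proposal
  scales adapted in batches of 50 during burn-in toward a 0.44
  acceptance rate (adaptation stops at burn-in end, so retained draws
  come from a fixed kernel);
* per species, an additional block update of the whole abundance (and
  detection) coefficient vector with proposal covariance proportional
  to $(X'X)^{-1}$ — this follows the design's collinearity structure,
  which matters here because the treatment flag shifts the vegetation
  covariates and therefore correlates strongly with them;
* a joint "ridge" move shifting every species' abundance intercept
  (and $\mu_{\beta_0}$) by $+d$ and every detection intercept (and
  $\mu_{\alpha_0}$) by $-d$: the product $\lambda\varphi$ is far better
  identified than its factors, and this move walks along that ridge
  with a full likelihood evaluation;
* hyper-means: exact conjugate Normal (Gibbs) updates;
* hyper-sds and $\sigma_{\text{site}}$: random walk on the log scale
  with the half-Normal prior and log-scale Jacobian;
* joint recentering moves for coefficients that are confounded with the
  site effects (the abundance intercept, and any site-constant 0/1
  covariate such as the treatment flag): propose shifting all affected
  $\gamma_t$ by $-d$ and the coefficient by $+d$ in every species.  The
  likelihood is exactly invariant along this direction, so only the
  priors enter the acceptance ratio; without these moves the
  intercept and treatment hyper-means random-walk along a posterior
  ridge and their $\hat R$ can sit above 1.1 at desk-scale budgets.

Initialization follows the observed data: hyper-means at 0, scales at
1, $\psi_i$ at the observed proportion of non-zero cells per species,
all jittered per chain; a non-finite starting log-posterior triggers
reinitialization. Multiple independent chains (default 3) are run from
different seeds; convergence is assessed with the classic Gelman–Rubin
$\hat R$ (between/within-chain variance ratio) with the conventional
$\hat R < 1.1$ bar, and a degenerate flag instead of a crash when every
chain has zero variance. Coefficients whose 95% equal-tailed credible
interval (default empirical quantile rule) excludes zero are flagged as
informative; intervals overlapping zero are read as uninformative.

**Iteration budgets.** The historical budget for this model family
(hundreds of thousands of Gibbs iterations with heavy thinning) is
unnecessary under exact marginalization. Package defaults are desk
scale: 3 chains × 4000 iterations, 1500 burn-in, thin 5. The recovery
studies in the test suite and `scripts/acceptance.R` use 2 chains ×
2000 iterations (burn-in 800, thin 3) on the one-year reference design
— at that budget all monitored hyper-parameters reach $\hat R < 1.1$
and 95% intervals cover the generating hyper-means at nominal rates.
Longer budgets are one `mcmc_config()` call away.

# Derived quantities

* **Detection probability** $P_d$: inverse-logit of the species
  detection intercept, i.e. detection at mean survey conditions — with
  centered covariates the intercept is the natural summary point.
  Suite and community values are unweighted means over member species
  *within each draw*, so their intervals propagate full uncertainty.
* **Zero-inflation** $\psi$: same aggregation over the posterior
  $\psi_i$ draws.
* **z-matrix**: per draw, $z_{is} = 1$ iff latent abundance is positive
  in at least one year at the point. Observed presences force $z = 1$;
  all-zero cells draw the latent state from its closed-form
  conditional. The point-level (not point × year) definition matches
  the co-occurrence question: "do these species use the same places?"
* **Jaccard co-occurrence** $J_{ij} = \sum z_i z_j / (\sum z_i + \sum
  z_j - \sum z_i z_j)$ computed per draw for all pairs (66 pairs for 12
  species), then summarized. A draw where both species are absent
  everywhere leaves $J$ undefined; such draws are dropped from that
  pair's summary and counted in `n_dropped`.
* **Suite summaries**: suite-level coefficients are derived means over
  member species draws rather than separate suite hyperpriors — one
  community hyperdistribution plus derived suite columns keeps the
  model identified with a single-species suite in the pool.
* **Natural-scale translation**: `rescale_effect()` converts a
  standardized coefficient into birds-per-plot change for a raw
  covariate change, taking the covariate sd and baseline abundance as
  explicit inputs (they depend on survey geometry and data, so the
  package does not guess them).

# The synthetic-data generator

`simulate_community()` generates data with exactly the structure the
model assumes, emulating the reference field design: 150 points across
18 sites (75 treatment / 75 control; the per-site split is
configuration since only the totals are fixed by the design), 3 visits
per year, 4 survey years, 12 species in three habitat suites (6
Forested Upland, 5 Scrub-Shrub, 1 Grassland).

Vegetation covariates are drawn per point × year from truncated normal
distributions per treatment group, parameterized by the observed group
mean, sd and range (truncated normal is the minimal family matching
all three reported statistics). Treatment stands carry more grass and
much less woody cover, visual obstruction and basal area than
controls. Visit dates are uniform over a 16 May – 10 Aug season
(day-of-season 0–86), wind uniform on 0–15 km/h (surveys stop above
that), disturbance on the 0–4 integer scale — only the collection
protocol, not the distributions, is documented for these, so simple
supports are used. Distance classes are not simulated: the reference
analysis pooled the 0–50 m and 50–100 m bins, so the generator emits
pooled 0–100 m counts directly.

Default hyperparameters give a community of moderately common species
(median $\lambda \approx 1.5$ birds/plot, mean observed count
$\approx 0.3$ per survey per species), detection near 0.18 at mean
conditions ($\mu_{\alpha_0} = -1.5$), a strong negative basal-area
effect ($\mu_{\beta,\text{basal}} = -0.4$, hyper-sd 0.3) and
zero-inflation $\psi = 0.6$ — the conditions used throughout the
recovery studies.

What the generator does **not** emulate: spatial autocorrelation
beyond the site effect, territoriality or movement, distance-dependent
detection, year-to-year vegetation dynamics, observer heterogeneity.
Passing recovery tests therefore demonstrate that the estimator is
correct *under its own assumptions*, not that those assumptions hold
in any particular field system.

# Covariate preparation

Continuous covariates are standardized (mean 0, sample sd 1, divisor
$n-1$) over all point × year records pooled — the model uses one design
matrix, so one standardization population. The squared date term is
the square of the standardized date (not re-standardized). The
treatment flag stays 0/1. Collinearity screening is greedy on
Pearson correlations: covariates are walked in priority order (basal >
grass > woody > VOR2 > rest — basal area first because it is the
standard forest-management measurement) and a candidate is dropped
when $|r| > 0.7$ with anything already retained, with every exclusion
and its trigger reported. Treatment/control covariate contrasts use
Welch's unequal-variance t-test with its honest degrees of freedom.
Records with missing model covariates are dropped with a logged count;
no imputation.

# Numerical and degenerate-input choices

* `standardize()` refuses constant covariates (sd = 0) — they carry no
  information and would divide by zero.
* `cell_marginal_loglik()` returns $-\infty$ (not an error) for a
  positive count under $\psi = 0$: a structurally impossible
  observation has zero likelihood.
* Detection probabilities are clamped to $[10^{-12}, 1-10^{-12}]$
  inside the likelihood so boundary inputs ($\varphi \in \{0,1\}$)
  remain well-defined.
* An undefined Jaccard draw (both species absent) is `NA`, never 0:
  absence of both species is no evidence about similarity.
* Proposal adaptation uses diminishing steps
  ($\min(0.1, 1/\sqrt{\text{batch}})$) and freezes at the end of
  burn-in.

# Known limitations

* Balanced designs only: every species × point × year × visit must be
  present once. Ragged visit histories are rejected, not imputed.
* The site random effect is shared across species; a species-specific
  $\gamma_{it}$ would need more data than the reference design
  provides.
* Scalar random-walk updates scale linearly in parameters; for much
  larger communities (hundreds of species) a gradient-based sampler on
  the same marginalized likelihood would be preferable. The likelihood
  is exposed as a pure function (`total_loglik`) for exactly that use.
* $t$-tests on point × year vegetation records treat repeated
  measurements of a point as independent; their p-values are
  descriptive, not central to the model.
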