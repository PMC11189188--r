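# Independent brute-force oracles and small fixtures, built in code.

# cell likelihood by exhaustive enumeration over the inclusion indicator
# a and the latent abundance M (linear-space products of stats densities)
oracle_cell_loglik <- function(y, psi, lambda, phi, K = 400) {
  phi <- rep_len(phi, length(y))
  S <- 0
  for (M in 0:K)
    S <- S + dpois(M, lambda) * prod(dbinom(y, M, phi))
  log((1 - psi) * all(y == 0) + psi * S)
}

# set-based Jaccard oracle
oracle_jaccard <- function(zi, zj) {
  a <- which(zi > 0)
  b <- which(zj > 0)
  u <- union(a, b)
  if (length(u) == 0) return(NA_real_)
  length(intersect(a, b)) / length(u)
}

# Welch statistic from first principles
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, df = df)
}

tiny_design <- function(n_species = 3, n_sites = 2, points_per_site = 5,
                        n_years = 1, visits = 3) {
  suites <- default_suites()[seq_len(n_species)]
  survey_design(n_sites = n_sites, points_per_site = points_per_site,
                n_years = n_years, visits_per_year = visits, suites = suites)
}

tiny_sim <- function(seed = 1, ...) {
  simulate_community(tiny_design(...), covariate_regime(),
                     community_hyperparams(), seed = seed)
}

# a comm_nmix-shaped object with hand-set posterior draws, for testing the
# derived-quantity operations in isolation
fake_fit <- function(counts, covariates, spec = model_spec(), draws,
                     n_chains = 1, suites = NULL) {
  dat <- commNmix:::build_model_data(counts, covariates, spec)
  a <- array(rep(draws, n_chains),
             dim = c(nrow(draws), ncol(draws), n_chains),
             dimnames = list(NULL, colnames(draws), NULL))
  class(a) <- "cnm_draws"
  structure(list(draws = a, data = dat, spec = spec,
                 config = mcmc_config(n_chains = n_chains, n_iter = 2,
                                      n_burnin = 0, thin = 1),
                 suites = suites, covariates = covariates),
            class = "comm_nmix")
}
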