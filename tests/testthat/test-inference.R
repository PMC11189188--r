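test_that("Gelman-Rubin diagnostics separate converged from divergent chains", {
  set.seed(42)
  same <- array(rnorm(1000 * 3 * 2), dim = c(1000, 3, 2),
                dimnames = list(NULL, c("a", "b", "c"), NULL))
  r <- gelman_rubin(same)
  expect_true(all(r >= 0.99 & r <= 1.05))
  # two chains offset by 10 sd are flagrantly non-converged
  off <- array(c(rnorm(500), rnorm(500, 10)), dim = c(500, 1, 2),
               dimnames = list(NULL, "a", NULL))
  expect_gt(gelman_rubin(off)["a"], 1.1)
  # constant chains: degenerate flag rather than a crash
  const <- array(1, dim = c(50, 1, 2), dimnames = list(NULL, "a", NULL))
  rc <- gelman_rubin(const)
  expect_true(is.na(rc["a"]))
  expect_true(attr(rc, "degenerate")["a"])
  expect_error(gelman_rubin(same[, , 1, drop = FALSE]), "2 chains")
  expect_error(gelman_rubin(same[1:5, , , drop = FALSE]), "draws")
})

test_that("posterior summaries use equal-tailed quantiles and the CrI rule", {
  x <- array(1:100, dim = c(100, 1, 1), dimnames = list(NULL, "a", NULL))
  s <- posterior_summary(x)
  expect_equal(s$lower, 3.475)
  expect_equal(s$upper, 97.525)
  expect_equal(s$mean, 50.5)
  expect_true(s$significant)       # all draws positive
  sym <- array(rep(c(-3, -1, 1, 3), 50), dim = c(200, 1, 2),
               dimnames = list(NULL, "b", NULL))
  expect_false(posterior_summary(sym)$significant)
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  sim <- tiny_sim(seed = 8, n_species = 2, points_per_site = 4, visits = 2)
  cfg <- mcmc_config(n_chains = 2, n_iter = 60, n_burnin = 20, thin = 2,
                     seed = 99)
  d1 <- run_mcmc(sim$counts, sim$covariates, config = cfg)
  d2 <- run_mcmc(sim$counts, sim$covariates, config = cfg)
  expect_identical(d1, d2)
  expect_equal(dim(d1)[1], (60 - 20) / 2)
  expect_equal(dim(d1)[3], 2)
  expect_true(all(is.finite(d1)))
})

test_that("all-zero data pulls the inclusion probability below its prior mean", {
  sim <- tiny_sim(seed = 12, n_species = 2, points_per_site = 10)
  zero <- sim$counts
  zero$count <- 0L
  fit <- comm_nmix(zero, sim$covariates,
                   config = mcmc_config(n_chains = 2, n_iter = 600,
                                        n_burnin = 300, thin = 3, seed = 4))
  psi <- commNmix:::pooled_draws(fit, paste0("psi[", fit$data$species, "]"))
  expect_lt(mean(psi), 0.5)   # Beta(1, 1) prior mean
})

test_that("a prior-only run recovers the prior for the hyper-means", {
  des <- tiny_design(n_species = 3, points_per_site = 3, visits = 2)
  cov <- prepare_covariates(generate_covariates(des, covariate_regime(),
                                                seed = 1))
  fit <- comm_nmix(NULL, cov, species = c("A", "B", "C"),
                   config = mcmc_config(n_chains = 1, n_iter = 30000,
                                        n_burnin = 2000, thin = 10, seed = 2))
  mu <- commNmix:::pooled_draws(fit, "mu_beta0")[, 1]
  # prior is Normal(0, sd ~ 31.6); the chain must wander far beyond any
  # data-informed scale and stay centered
  expect_gt(sd(mu), 15)
  expect_lt(sd(mu), 55)
  expect_lt(abs(mean(mu)), 12)
  sg <- commNmix:::pooled_draws(fit, "sigma_beta0")[, 1]
  expect_lt(abs(mean(sg) - 2 * sqrt(2 / pi)), 0.25)  # half-Normal(2) mean
  ps <- commNmix:::pooled_draws(fit, "psi[A]")[, 1]
  expect_lt(abs(mean(ps) - 0.5), 0.05)               # Beta(1, 1) mean
})

test_that("mcmc_config validates its invariants", {
  expect_error(mcmc_config(n_burnin = 10, n_iter = 10), "n_burnin")
  expect_error(mcmc_config(n_iter = 11, n_burnin = 0, thin = 2))
  expect_s3_class(mcmc_config(), "cnm_mcmc_config")
})
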