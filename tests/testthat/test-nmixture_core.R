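test_that("linear predictors map to abundance and detection scales", {
  expect_equal(linear_abundance(0), 1)
  expect_equal(linear_abundance(log(2)), 2)
  # one-covariate spot value at +1 sd of basal area
  expect_equal(linear_abundance(0, -0.23, 1), exp(-0.23))
  expect_equal(linear_detection(0), 0.5)
  expect_equal(linear_detection(-1.71), plogis(-1.71))
  expect_lt(linear_detection(-1.71), 0.16)   # consistent with low detectability
  expect_equal(linear_detection(-1e4), 0)    # boundary limit
  expect_error(linear_abundance(1, c(1, 2), 1), "conform")
})

test_that("marginal cell likelihood matches exhaustive enumeration", {
  set.seed(101)
  worst <- 0
  for (i in 1:1200) {
    V <- sample(1:3, 1)
    y <- sample(0:4, V, replace = TRUE)
    lambda <- runif(1, 0.05, 3)
    phi <- runif(V, 0.02, 0.98)
    psi <- runif(1)
    got <- cell_marginal_loglik(y, psi, lambda, phi)
    want <- oracle_cell_loglik(y, psi, lambda, phi)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-10)
})

test_that("all-zero cells obey the closed-form identity", {
  set.seed(5)
  for (i in 1:300) {
    V <- sample(1:4, 1)
    lambda <- runif(1, 0.01, 8)
    phi <- runif(V, 0.01, 0.99)
    psi <- runif(1)
    q <- prod(1 - phi)
    closed <- log((1 - psi) + psi * exp(-lambda * (1 - q)))
    got <- cell_marginal_loglik(rep(0, V), psi, lambda, phi)
    expect_lt(abs(got - closed), 1e-10)
  }
  # structural zero: psi = 0 and all-zero counts has likelihood exactly 1
  expect_equal(cell_marginal_loglik(c(0, 0, 0), 0, 2, 0.3), 0)
  # psi = 0 with a positive count is impossible
  expect_identical(cell_marginal_loglik(c(1, 0), 0, 2, 0.3), -Inf)
})

test_that("zero-inflated marginal reduces to the plain N-mixture at psi = 1", {
  set.seed(17)
  for (i in 1:200) {
    V <- sample(1:3, 1)
    y <- sample(0:5, V, replace = TRUE)
    lambda <- runif(1, 0.1, 4)
    phi <- runif(V, 0.05, 0.95)
    expect_lt(abs(cell_marginal_loglik(y, 1, lambda, phi) -
                    nmix_cell_loglik(y, lambda, phi)), 1e-10)
  }
})

test_that("truncation is stable and visit order is irrelevant", {
  set.seed(23)
  for (i in 1:50) {
    y <- sample(0:3, 3, replace = TRUE)
    lambda <- runif(1, 0.2, 4)
    phi <- runif(3, 0.1, 0.9)
    auto <- cell_marginal_loglik(y, 0.7, lambda, phi)
    forced <- cell_marginal_loglik(y, 0.7, lambda, phi, K = 280)
    expect_lt(abs(auto - forced), 1e-8)
    perm <- sample(3)
    expect_equal(cell_marginal_loglik(y[perm], 0.7, lambda, phi[perm]), auto)
  }
  expect_error(cell_marginal_loglik(c(5, 1), 0.5, 2, 0.5, K = 3), "max")
  expect_error(cell_marginal_loglik(c(-1, 0), 0.5, 2, 0.5), "non-negative")
  expect_error(cell_marginal_loglik(c(0, 0), 1.5, 2, 0.5), "psi")
})

test_that("total log-likelihood is additive and favors the truth", {
  sim <- tiny_sim(seed = 31)
  empty <- sim$counts[0, ]
  expect_equal(total_loglik(empty, sim$covariates, sim$params), 0)

  # per-cell additivity: the total is the sum of the cell contributions
  des2 <- survey_design(n_sites = 1, points_per_site = 3, n_years = 1,
                        visits_per_year = 2, suites = default_suites()[1],
                        treatment = "control")
  cov2 <- prepare_covariates(generate_covariates(des2, covariate_regime(),
                                                 seed = 2))
  p2 <- draw_species_params(community_hyperparams(), des2, seed = 3)
  y2 <- simulate_counts(p2, cov2, des2, seed = 4)
  tot <- total_loglik(y2, cov2, p2)
  manual <- 0
  for (cell in seq_len(3)) {
    sub <- y2[y2$point == cell, ]
    x <- unlist(cov2$points_z[cell, colnames(p2$beta)])
    lam <- linear_abundance(p2$beta0[1], p2$beta[1, ], x, p2$gamma[1])
    vz <- cov2$visits_z[cov2$visits_z$point == cell, colnames(p2$alpha)]
    phi <- apply(vz, 1, function(v) linear_detection(p2$alpha0[1],
                                                     p2$alpha[1, ], v))
    manual <- manual + cell_marginal_loglik(sub$count[order(sub$visit)],
                                            p2$psi[1], lam,
                                            phi[order(sub$visit)])
  }
  expect_equal(tot, manual, tolerance = 1e-9)

  # likelihood consistency: true parameters beat a badly shifted copy
  wins <- 0
  for (r in 1:60) {
    s <- tiny_sim(seed = 100 + r)
    bad <- s$params
    bad$beta[, "basal"] <- bad$beta[, "basal"] + 2
    ll_true <- total_loglik(s$counts, s$covariates, s$params)
    ll_bad <- total_loglik(s$counts, s$covariates, bad)
    wins <- wins + (ll_true > ll_bad)
  }
  expect_gte(wins, 57)  # >= 95% of replicates
})

test_that("log-prior matches its closed form and is additive in species", {
  spec <- model_spec()
  des <- tiny_design(n_species = 2)
  h <- community_hyperparams()
  mk <- function(des) {
    S <- des$n_species
    list(beta0 = setNames(rep(h$mu_beta0, S), des$species),
         beta = matrix(rep(h$mu_beta, each = S), S,
                       dimnames = list(des$species, names(h$mu_beta))),
         alpha0 = setNames(rep(h$mu_alpha0, S), des$species),
         alpha = matrix(rep(h$mu_alpha, each = S), S,
                        dimnames = list(des$species, names(h$mu_alpha))),
         psi = setNames(rep(0.5, S), des$species),
         gamma = rep(0, des$n_sites))
  }
  p <- mk(des)
  lp <- log_prior(p, h, spec)
  nb <- length(h$mu_beta); na <- length(h$mu_alpha)
  hyper_term <- sum(dnorm(c(h$mu_beta0, h$mu_beta, h$mu_alpha0, h$mu_alpha),
                          0, sqrt(1000), log = TRUE)) +
    sum(log(2) + dnorm(c(h$sigma_beta0, h$sigma_beta, h$sigma_alpha0,
                         h$sigma_alpha, h$sigma_site), 0, 2, log = TRUE))
  species_term <- 2 * (dnorm(0, 0, h$sigma_beta0, log = TRUE) +
                         sum(dnorm(0, 0, h$sigma_beta, log = TRUE)) +
                         dnorm(0, 0, h$sigma_alpha0, log = TRUE) +
                         sum(dnorm(0, 0, h$sigma_alpha, log = TRUE)))
  site_term <- 2 * dnorm(0, 0, h$sigma_site, log = TRUE)
  expect_equal(lp, hyper_term + species_term + site_term, tolerance = 1e-10)

  # doubling the species doubles the species-level term
  des4 <- tiny_design(n_species = 4)
  p4 <- mk(des4)
  p4$gamma <- p$gamma
  lp4 <- log_prior(p4, h, spec)
  expect_equal(lp4 - hyper_term - site_term,
               2 * (lp - hyper_term - site_term), tolerance = 1e-10)

  h_bad <- h
  h_bad$sigma_beta0 <- -1
  expect_identical(log_prior(p, h_bad, spec), -Inf)
  p_bad <- p
  p_bad$psi[1] <- 1.5
  expect_identical(log_prior(p_bad, h, spec), -Inf)
})
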