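test_that("survey design validates and counts its surveys", {
  d <- survey_design()
  expect_equal(d$n_points, 150L)
  expect_equal(d$n_surveys, 1800L)
  expect_equal(sum(d$point_treatment == "treatment"), 75L)
  expect_equal(sum(d$point_treatment == "control"), 75L)
  d2 <- survey_design(n_sites = 3, points_per_site = 4, n_years = 2,
                      visits_per_year = 3, suites = default_suites()[1:2],
                      treatment = c("treatment", "control", "control"))
  expect_equal(d2$n_surveys, 3L * 4L * 2L * 3L)
  expect_error(survey_design(points_per_site = c(1, 2)), "points_per_site")
})

test_that("covariate generation honors the truncated-normal regimes", {
  reg <- covariate_regime()
  des <- survey_design(n_sites = 2, points_per_site = 150, n_years = 1,
                       visits_per_year = 3, suites = default_suites()[1:2],
                       treatment = c("control", "treatment"))
  cov <- generate_covariates(des, reg, seed = 101)
  pts <- cov$points
  expect_true(all(pts$grass >= 0 & pts$grass <= 100))
  expect_true(all(pts$basal >= 0))
  ctrl <- pts[pts$treatment == "control", ]
  expect_equal(nrow(ctrl), 150)
  # control basal: mean 28.89, sd 9.83 on [3.44, 65.04]; truncation barely
  # shifts the mean, so the sample mean at n = 150 stays within 3 SE
  expect_lt(abs(mean(ctrl$basal) - 28.89), 3 * 9.83 / sqrt(150))
  expect_true(all(ctrl$basal >= 3.44 & ctrl$basal <= 65.04))
  # degenerate regime: sd = 0 gives the group mean everywhere
  reg0 <- covariate_regime(abundance = within(default_abundance_regime(),
                                              sd <- 0))
  cov0 <- generate_covariates(des, reg0, seed = 1)
  expect_true(all(cov0$points$basal %in% c(28.89, 9.45)))
  # determinism
  expect_identical(generate_covariates(des, reg, seed = 7),
                   generate_covariates(des, reg, seed = 7))
})

test_that("infeasible regimes are rejected with the covariate named", {
  bad <- default_abundance_regime()
  bad$mean[bad$covariate == "grass" & bad$group == "control"] <- 20 # > upper 15
  expect_error(covariate_regime(abundance = bad), "grass")
})

test_that("species parameters follow their hyperdistributions", {
  des <- tiny_design()
  # point-mass hyperpriors: every species equals the community mean
  h0 <- community_hyperparams(sigma_beta0 = 0, sigma_beta = 0,
                              sigma_alpha0 = 0, sigma_alpha = 0,
                              sigma_site = 0)
  p0 <- draw_species_params(h0, des, seed = 1)
  expect_true(all(p0$beta0 == h0$mu_beta0))
  expect_true(all(p0$beta[, "basal"] == h0$mu_beta["basal"]))
  expect_true(all(p0$gamma == 0))
  # large-sample moments
  des_many <- survey_design(n_sites = 1, points_per_site = 1, n_years = 1,
                            visits_per_year = 1,
                            suites = setNames(rep("Grassland", 10000),
                                              paste0("sp", 1:10000)),
                            treatment = "control")
  h <- community_hyperparams(mu_beta0 = 1, sigma_beta0 = 0.5)
  p <- draw_species_params(h, des_many, seed = 2)
  expect_lt(abs(mean(p$beta0) - 1), 4 * 0.5 / sqrt(10000))
  expect_lt(abs(sd(p$beta0) - 0.5), 0.02)
})

test_that("count simulation obeys the process model structure", {
  sim <- tiny_sim(seed = 5)
  truth <- attr(sim$counts, "truth")
  expect_true(all(sim$counts$count >= 0))
  expect_true(all(sim$counts$count == floor(sim$counts$count)))
  # per cell, max over visits of y never exceeds the latent abundance M
  for (sp in rownames(truth$M)) {
    sub <- sim$counts[sim$counts$species == sp, ]
    ymax <- tapply(sub$count, paste(sub$point, sub$year), max)
    cells <- paste(sim$covariates$points_z$point, sim$covariates$points_z$year)
    expect_true(all(ymax[cells] <= truth$M[sp, ]))
  }
  # full zero-inflation: psi = 0 silences a species completely
  h0 <- community_hyperparams(psi = 0)
  des <- tiny_design()
  cov <- sim$covariates
  p <- draw_species_params(h0, des, seed = 3)
  y0 <- simulate_counts(p, cov, des, seed = 4)
  expect_true(all(y0$count == 0))
  # perfect detection: every visit count equals M
  h1 <- community_hyperparams(psi = 1)
  p1 <- draw_species_params(h1, des, seed = 3)
  y1 <- simulate_counts(p1, cov, des, seed = 4, phi_fixed = 1)
  tr1 <- attr(y1, "truth")
  M_long <- tr1$M[cbind(match(y1$species, rownames(tr1$M)),
                        match(paste(y1$point, y1$year),
                              paste(cov$points_z$point, cov$points_z$year)))]
  expect_identical(as.integer(y1$count), as.integer(M_long))
  # determinism of the full dataset
  expect_identical(simulate_counts(p1, cov, des, seed = 9),
                   simulate_counts(p1, cov, des, seed = 9))
})

test_that("thinned-Poisson identity: marginal visit counts have mean lambda*phi", {
  # psi = 1, constant lambda = 2 (all slopes zero), constant phi = 0.5
  des <- survey_design(n_sites = 2, points_per_site = 5000, n_years = 1,
                       visits_per_year = 3, suites = default_suites()[1],
                       treatment = c("control", "treatment"))
  h <- community_hyperparams(mu_beta0 = log(2), sigma_beta0 = 0,
                             mu_beta = c(grass = 0, woody = 0, vor2 = 0,
                                         basal = 0, treatment = 0),
                             sigma_beta = 0, mu_alpha0 = 0, sigma_alpha0 = 0,
                             mu_alpha = c(date = 0, date2 = 0, wind = 0,
                                          disturbance = 0),
                             sigma_alpha = 0, psi = 1, sigma_site = 0)
  cov <- generate_covariates(des, covariate_regime(), seed = 21)
  p <- draw_species_params(h, des, seed = 22)
  y <- simulate_counts(p, cov, des, seed = 23)
  # y ~ Poisson(2) thinned at 0.5 => mean 1, var 1
  n <- nrow(y)
  expect_lt(abs(mean(y$count) - 1), 4 / sqrt(n))
})
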