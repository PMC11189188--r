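mk_draws <- function(dat, D, overrides = list()) {
  cols <- c(paste0("mu_", c(dat$ab_labels, dat$det_labels)),
            paste0("sigma_", c(dat$ab_labels, dat$det_labels)), "sigma_site",
            unlist(lapply(c(dat$ab_labels, dat$det_labels),
                          function(l) paste0(l, "[", dat$species, "]"))),
            paste0("psi[", dat$species, "]"),
            paste0("gamma[", dat$sites, "]"))
  m <- matrix(0, D, length(cols), dimnames = list(NULL, cols))
  for (nm in names(overrides)) m[, nm] <- overrides[[nm]]
  m
}

derived_fixture <- function(seed = 3) {
  des <- survey_design(n_sites = 2, points_per_site = 2, n_years = 1,
                       visits_per_year = 3,
                       suites = c(A = "Forested Upland", B = "Forested Upland",
                                  C = "Scrub-Shrub"),
                       treatment = c("treatment", "control"))
  cov <- prepare_covariates(generate_covariates(des, covariate_regime(),
                                                seed = seed))
  p <- draw_species_params(community_hyperparams(), des, seed = seed)
  counts <- simulate_counts(p, cov, des, seed = seed)
  list(des = des, cov = cov, counts = counts)
}

test_that("detection probability aggregates species -> suite -> community", {
  fx <- derived_fixture()
  dat <- commNmix:::build_model_data(fx$counts, fx$cov, model_spec())
  dr <- mk_draws(dat, 50, list("alpha0[A]" = 0, "alpha0[B]" = -1.71,
                               "alpha0[C]" = -1.71))
  fit <- fake_fit(fx$counts, fx$cov, draws = dr)
  fit$suites <- fx$des$suites
  ds <- detection_summary(fit)
  g <- function(lv, nm) ds[ds$level == lv & ds$name == nm, ]
  expect_equal(g("species", "A")$mean, 0.5)
  expect_equal(g("species", "B")$mean, plogis(-1.71), tolerance = 1e-12)
  expect_lt(abs(g("species", "B")$mean - 0.153), 5e-4)
  # suite mean of members; single-species suite equals the species
  expect_equal(g("suite", "Forested Upland")$mean,
               mean(c(0.5, plogis(-1.71))))
  expect_equal(g("suite", "Scrub-Shrub")$mean, plogis(-1.71))
  # community is the unweighted per-draw mean over species
  expect_equal(g("community", "community")$mean,
               mean(c(0.5, plogis(-1.71), plogis(-1.71))))
  # point-mass draws give zero-width intervals
  expect_equal(g("species", "A")$lower, g("species", "A")$upper)
  fit$suites <- NULL
  expect_error(detection_summary(fit), "suite")
})

test_that("zero-inflation summaries mirror psi draws", {
  fx <- derived_fixture()
  dat <- commNmix:::build_model_data(fx$counts, fx$cov, model_spec())
  set.seed(2)
  u <- runif(4000)
  dr <- mk_draws(dat, 4000, list("psi[A]" = 1, "psi[B]" = 1, "psi[C]" = u))
  fit <- fake_fit(fx$counts, fx$cov, draws = dr)
  fit$suites <- fx$des$suites
  zs <- zero_inflation_summary(fit)
  g <- function(lv, nm) zs[zs$level == lv & zs$name == nm, ]
  expect_equal(g("species", "A")$mean, 1)
  expect_equal(g("suite", "Scrub-Shrub")$mean, mean(u))
  expect_lt(abs(g("suite", "Scrub-Shrub")$mean - 0.5), 4 * 0.29 / sqrt(4000))
})

test_that("jaccard matches hand enumeration and the set oracle", {
  expect_equal(jaccard(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(jaccard(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_true(is.na(jaccard(c(0, 0), c(0, 0))))
  expect_error(jaccard(c(1, 0), c(1, 0, 1)), "length")
  set.seed(9)
  agrees <- symmetric <- TRUE
  for (i in 1:1000) {
    zi <- rbinom(12, 1, runif(1))
    zj <- rbinom(12, 1, runif(1))
    j <- jaccard(zi, zj)
    agrees <- agrees && identical(j, oracle_jaccard(zi, zj))
    symmetric <- symmetric && identical(j, jaccard(zj, zi))
  }
  expect_true(agrees)
  expect_true(symmetric)
})

test_that("posterior Jaccard summaries cover all pairs with propagated uncertainty", {
  S <- 12; P <- 20; D <- 30
  set.seed(4)
  zconst <- array(rep(rbinom(S * P, 1, 0.5), each = D), dim = c(D, S, P),
                  dimnames = list(NULL, paste0("sp", 1:S), paste0("p", 1:P)))
  class(zconst) <- "cnm_zmatrix"
  js <- jaccard_posterior(zconst)
  expect_equal(nrow(js), 66)           # 12 * 11 / 2 pairs
  expect_true(all(js$mean >= 0 & js$mean <= 1, na.rm = TRUE))
  expect_equal(js$lower, js$upper)     # constant z -> zero-width CrIs
  # two species that always co-occur
  z2 <- array(0L, dim = c(D, 2, P), dimnames = list(NULL, c("a", "b"), NULL))
  occ <- matrix(rbinom(D * P, 1, 0.6), D, P)
  z2[, 1, ] <- occ; z2[, 2, ] <- occ
  z2[, 1, 1] <- 1; z2[, 2, 1] <- 1     # never undefined
  class(z2) <- "cnm_zmatrix"
  j2 <- jaccard_posterior(z2)
  expect_equal(j2$mean, 1)
  expect_equal(j2$lower, 1)
  expect_equal(j2$upper, 1)
  expect_equal(j2$n_dropped, 0)
})

test_that("z-matrix construction honors observations and the latent conditional", {
  fx <- derived_fixture(seed = 6)
  dat <- commNmix:::build_model_data(fx$counts, fx$cov, model_spec())
  lam <- 1.5; phi <- 0.4; psi <- 0.7
  D <- 4000
  dr <- mk_draws(dat, D, setNames(
    list(log(lam), log(lam), log(lam), qlogis(phi), qlogis(phi), qlogis(phi),
         psi, psi, psi),
    c(paste0("beta0[", dat$species, "]"),
      paste0("alpha0[", dat$species, "]"),
      paste0("psi[", dat$species, "]"))))
  fit <- fake_fit(fx$counts, fx$cov, draws = dr)
  fit$suites <- fx$des$suites
  z <- build_z_matrix(fit, n_draws = D, seed = 31)
  # observed points are occupied in every draw
  for (s in seq_along(dat$species)) {
    sp <- dat$species[s]
    seen <- tapply(colSums(dat$Yt[[sp]]) > 0, dat$cells$point, any)
    for (pt in names(seen)[seen])
      expect_true(all(z[, s, paste0("p", pt)] == 1))
    # all-zero points follow the closed-form conditional within MC error
    q <- (1 - phi)^3
    pz <- psi * (exp(-lam * (1 - q)) - exp(-lam)) /
      ((1 - psi) + psi * exp(-lam * (1 - q)))
    for (pt in names(seen)[!seen]) {
      zb <- mean(z[, s, paste0("p", pt)])
      expect_lt(abs(zb - pz), 4 * sqrt(pz * (1 - pz) / D) + 1e-6)
    }
  }
  # a psi = 0 species with all-zero counts is absent everywhere
  zero <- fx$counts; zero$count <- 0L
  dr0 <- mk_draws(dat, 100)
  dr0[, paste0("psi[", dat$species, "]")] <- 0
  fit0 <- fake_fit(zero, fx$cov, draws = dr0)
  z0 <- build_z_matrix(fit0, n_draws = 100, seed = 1)
  expect_true(all(z0 == 0))
})

test_that("suite summaries derive from member species draws", {
  fx <- derived_fixture()
  dat <- commNmix:::build_model_data(fx$counts, fx$cov, model_spec())
  # A and B (same suite) carry opposite coefficients in every draw
  dr <- mk_draws(dat, 40, list("beta_basal[A]" = 0.8, "beta_basal[B]" = -0.8,
                               "beta_basal[C]" = -0.3, "mu_beta_basal" = -0.1))
  fit <- fake_fit(fx$counts, fx$cov, draws = dr)
  fit$suites <- fx$des$suites
  ss <- suite_summary(fit, labels = "beta_basal")
  fu <- ss[ss$level == "suite" & ss$name == "Forested Upland", ]
  expect_equal(fu$mean, 0)
  expect_false(fu$significant)
  sc <- ss[ss$level == "suite" & ss$name == "Scrub-Shrub", ]
  expect_equal(sc$mean, -0.3)       # one-species suite equals the species
  expect_true(sc$significant)
  com <- ss[ss$level == "community", ]
  expect_equal(com$mean, -0.1)      # community row is the hyper-mean draw
})

test_that("natural-scale effect translation follows its formula", {
  expect_equal(rescale_effect(0, 13, -26, 2)$mean, 0)
  expect_equal(rescale_effect(-0.23, 13, 0, 2)$mean, 0)
  r <- rescale_effect(-0.23, 13, -26, 2)
  expect_equal(r$mean, 2 * (exp(0.46) - 1), tolerance = 1e-12)
  expect_lt(abs(r$mean - 1.17), 0.01)
  expect_error(rescale_effect(0.1, 0, 1), "positive")
  # uncertainty propagates draw-wise
  set.seed(1)
  b <- rnorm(500, -0.23, 0.05)
  r2 <- rescale_effect(b, 13, -26, 2)
  expect_equal(r2$draws, 2 * (exp(b * -26 / 13) - 1))
  expect_lt(r2$lower, r2$upper)
})
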