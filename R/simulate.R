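# truncated-normal draws via the inverse-CDF construction; sd = 0 collapses
# to a point mass at the mean
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal with mean outside bounds")
    return(rep(mean, n))
  }
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

#' Generate point- and visit-level covariates for a survey design
#'
#' Draws the four vegetation covariates (grass, woody, VOR2, basal) per
#' point x year from the truncated-normal regime of the point's treatment
#' group, and visit-level detection covariates (date as day-of-season,
#' wind, disturbance) from their supports.
#'
#' @param design A [survey_design()].
#' @param regime A [covariate_regime()].
#' @param seed Optional integer seed; a fixed seed reproduces the tables
#'   bit for bit.
#' @return An object of class `cnm_covariates`: a list with `points`
#'   (one row per point x year) and `visits` (one row per point x year x
#'   visit) data frames, both raw-scale.
#' @export
generate_covariates <- function(design, regime, seed = NULL) {
  stopifnot(inherits(design, "cnm_design"), inherits(regime, "cnm_regime"))
  if (!is.null(seed)) set.seed(seed)

  cells <- expand.grid(point = seq_len(design$n_points),
                       year = seq_len(design$n_years))
  cells$site <- design$point_site[cells$point]
  cells$treatment <- design$point_treatment[cells$point]

  covs <- unique(regime$abundance$covariate)
  for (cv in covs) {
    vals <- numeric(nrow(cells))
    for (grp in c("control", "treatment")) {
      row <- regime$abundance[regime$abundance$covariate == cv &
                                regime$abundance$group == grp, ]
      if (nrow(row) != 1)
        stop("regime must have exactly one ", grp, " row for covariate ", cv)
      idx <- cells$treatment == grp
      vals[idx] <- rtruncnorm(sum(idx), row$mean, row$sd, row$lower, row$upper)
    }
    cells[[cv]] <- vals
  }

  visits <- expand.grid(point = seq_len(design$n_points),
                        year = seq_len(design$n_years),
                        visit = seq_len(design$visits_per_year))
  nv <- nrow(visits)
  visits$date <- runif(nv, regime$date_range[1], regime$date_range[2])
  visits$wind <- runif(nv, regime$wind_range[1], regime$wind_range[2])
  visits$disturbance <- sample(regime$disturbance_levels, nv, replace = TRUE)

  out <- list(points = cells[, c("point", "site", "year", "treatment", covs)],
              visits = visits[, c("point", "year", "visit", "date", "wind",
                                  "disturbance")],
              standardized = FALSE)
  class(out) <- "cnm_covariates"
  out
}

#' Draw species-level parameters from community hyperdistributions
#'
#' Species coefficients are drawn independently from their Normal
#' hyperdistributions, site random effects from `N(0, sigma_site^2)`, and
#' zero-inflation probabilities either fixed or drawn from their Beta
#' hyperprior.
#'
#' @param hyper A [community_hyperparams()].
#' @param design A [survey_design()].
#' @param seed Optional integer seed.
#' @return An object of class `cnm_params`: list with `beta0`, `beta`
#'   (species x covariate matrix), `alpha0`, `alpha`, `psi`, `gamma`.
#' @export
draw_species_params <- function(hyper, design, seed = NULL) {
  stopifnot(inherits(hyper, "cnm_hyper"), inherits(design, "cnm_design"))
  if (!is.null(seed)) set.seed(seed)
  S <- design$n_species
  beta0 <- rnorm(S, hyper$mu_beta0, hyper$sigma_beta0)
  beta <- sapply(seq_along(hyper$mu_beta), function(k)
    rnorm(S, hyper$mu_beta[k], hyper$sigma_beta[k]))
  beta <- matrix(beta, nrow = S,
                 dimnames = list(design$species, names(hyper$mu_beta)))
  alpha0 <- rnorm(S, hyper$mu_alpha0, hyper$sigma_alpha0)
  alpha <- sapply(seq_along(hyper$mu_alpha), function(k)
    rnorm(S, hyper$mu_alpha[k], hyper$sigma_alpha[k]))
  alpha <- matrix(alpha, nrow = S,
                  dimnames = list(design$species, names(hyper$mu_alpha)))
  psi <- if (hyper$psi_beta) {
    stats::rbeta(S, hyper$psi[1], hyper$psi[2])
  } else {
    rep_len(hyper$psi, S)
  }
  gamma <- if (hyper$sigma_site == 0) rep(0, design$n_sites) else
    rnorm(design$n_sites, 0, hyper$sigma_site)
  out <- list(beta0 = setNames(beta0, design$species), beta = beta,
              alpha0 = setNames(alpha0, design$species), alpha = alpha,
              psi = setNames(psi, design$species), gamma = gamma)
  class(out) <- "cnm_params"
  out
}

#' Simulate repeated point-count data from the zero-inflated N-mixture model
#'
#' For each species x point x year, draws the inclusion indicator
#' `a ~ Bernoulli(psi_i)`, latent abundance `M ~ Poisson(a * lambda)` with
#' `log lambda = beta0_i + beta_i' x + gamma_site`, and per-visit counts
#' `y ~ Binomial(M, phi)` with `logit phi = alpha0_i + alpha_i' v`.
#' Covariates are standardized before entering the linear predictors.
#' The latent truth (`a`, `M`, `lambda`) is retained as an attribute.
#'
#' @param params A [draw_species_params()] result (or a hand-built list of
#'   the same shape).
#' @param covariates A `cnm_covariates` object (raw covariates are
#'   standardized internally via [prepare_covariates()]).
#' @param design A [survey_design()].
#' @param seed Optional integer seed.
#' @param phi_fixed Optional fixed detection probability in (0, 1]
#'   overriding the detection model (`phi_fixed = 1` gives perfect
#'   detection so every visit count equals `M`).
#' @return A data frame of class `cnm_counts` with columns `species`,
#'   `site`, `point`, `year`, `visit`, `count`, plus a `"truth"` attribute
#'   holding the latent `a` and `M` matrices (species x cell).
#' @export
simulate_counts <- function(params, covariates, design, seed = NULL,
                            phi_fixed = NULL) {
  stopifnot(inherits(design, "cnm_design"))
  if (!isTRUE(covariates$standardized))
    covariates <- prepare_covariates(covariates)
  if (!is.null(seed)) set.seed(seed)

  ab_vars <- colnames(params$beta)
  det_vars <- colnames(params$alpha)
  Xab <- as.matrix(covariates$points_z[, ab_vars, drop = FALSE])
  Xdet <- as.matrix(covariates$visits_z[, det_vars, drop = FALSE])
  n <- nrow(Xab)
  V <- design$visits_per_year
  S <- design$n_species
  site <- covariates$points_z$site

  # visit rows aligned to cell rows: visits_z ordered visit-major
  a_mat <- matrix(0L, S, n, dimnames = list(design$species, NULL))
  M_mat <- matrix(0L, S, n, dimnames = list(design$species, NULL))
  counts <- vector("list", S)
  for (s in seq_len(S)) {
    eta <- params$beta0[s] + drop(Xab %*% params$beta[s, ]) + params$gamma[site]
    if (any(!is.finite(eta)))
      stop("non-finite abundance predictor for species ", design$species[s],
           " at cell ", which(!is.finite(eta))[1])
    lambda <- exp(eta)
    a <- rbinom(n, 1L, params$psi[s])
    M <- rpois(n, a * lambda)
    if (is.null(phi_fixed)) {
      eta_det <- params$alpha0[s] + drop(Xdet %*% params$alpha[s, ])
      if (any(!is.finite(eta_det)))
        stop("non-finite detection predictor for species ", design$species[s],
             " at visit row ", which(!is.finite(eta_det))[1])
      phi <- plogis(eta_det)
    } else {
      stopifnot(phi_fixed > 0, phi_fixed <= 1)
      phi <- rep(phi_fixed, n * V)
    }
    y <- rbinom(n * V, rep(M, V), phi)
    a_mat[s, ] <- a
    M_mat[s, ] <- M
    counts[[s]] <- data.frame(
      species = design$species[s],
      site = rep(site, V),
      point = rep(covariates$points_z$point, V),
      year = rep(covariates$points_z$year, V),
      visit = rep(seq_len(V), each = n),
      count = y, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, counts)
  rownames(out) <- NULL
  attr(out, "truth") <- list(a = a_mat, M = M_mat)
  class(out) <- c("cnm_counts", class(out))
  out
}

#' Simulate a complete community point-count dataset
#'
#' One-stop wrapper: draws covariates from the regime, species parameters
#' from the community hyperdistributions, and counts from the process
#' model, all reproducibly from a single seed.
#'
#' @inheritParams generate_covariates
#' @param hyper A [community_hyperparams()].
#' @param seed Integer seed controlling every draw.
#' @return List of class `cnm_sim` with `counts`, `covariates`
#'   (standardized), `params`, `hyper`, `design`.
#' @export
simulate_community <- function(design = survey_design(),
                               regime = covariate_regime(),
                               hyper = community_hyperparams(),
                               seed = 1L) {
  set.seed(seed)
  sub <- sample.int(2^31 - 2, 3)
  covariates <- generate_covariates(design, regime, seed = sub[1])
  covariates <- prepare_covariates(covariates)
  params <- draw_species_params(hyper, design, seed = sub[2])
  counts <- simulate_counts(params, covariates, design, seed = sub[3])
  out <- list(counts = counts, covariates = covariates, params = params,
              hyper = hyper, design = design, seed = seed)
  class(out) <- "cnm_sim"
  out
}
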