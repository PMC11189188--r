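#' MCMC configuration
#'
#' @param n_chains Number of independent chains (>= 2 for convergence
#'   assessment).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded (adaptation happens here).
#' @param thin Keep every `thin`-th post-burn-in iteration;
#'   `(n_iter - n_burnin)` must be divisible by `thin`.
#' @param seed Integer seed; fixes all chains bit for bit.
#' @param monitor Optional character vector of parameter names to monitor
#'   in summaries and convergence checks (default: all community
#'   hyperparameters).
#' @param adapt_interval Proposal adaptation batch length during burn-in.
#' @param init_retries Reinitialization attempts on a non-finite starting
#'   log-posterior.
#' @return An object of class `cnm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 4000, n_burnin = 1500,
                        thin = 5, seed = 1L, monitor = NULL,
                        adapt_interval = 50, init_retries = 20) {
  stopifnot(n_chains >= 1, n_iter >= 1, n_burnin >= 0, n_burnin < n_iter,
            thin >= 1, (n_iter - n_burnin) %% thin == 0, adapt_interval >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), monitor = monitor,
                 adapt_interval = as.integer(adapt_interval),
                 init_retries = as.integer(init_retries)),
            class = "cnm_mcmc_config")
}

# one chain of the adaptive Metropolis-within-Gibbs sampler
run_chain <- function(dat, spec, config, seed, verbose = FALSE) {
  set.seed(seed)
  p <- ncol(dat$Xab); q <- ncol(dat$Xdet)
  S <- dat$S; Tn <- length(dat$sites); n <- dat$n
  hs <- spec$hyper_sd_scale
  prior_prec <- spec$prior_precision

  pobs <- if (n > 0)
    vapply(dat$Yt, function(m) mean(colSums(m) > 0), numeric(1))
  else rep(0.5, S)
  pobs <- pmin(pmax(pobs, 0.05), 0.95)

  new_state <- function() list(
    beta = matrix(rnorm(p * S, 0, 0.1), p, S),
    alpha = matrix(rnorm(q * S, 0, 0.1), q, S),
    lpsi = qlogis(pobs) + rnorm(S, 0, 0.2),
    gamma = rnorm(Tn, 0, 0.1),
    mu_b = rep(0, p), sd_b = rep(1, p),
    mu_a = rep(0, q), sd_a = rep(1, q),
    sigma_site = 1)

  state_loglik <- function(st) {
    if (n == 0) return(0)
    tot <- 0
    for (s in seq_len(S)) {
      eta <- drop(dat$Xab %*% st$beta[, s]) + st$gamma[dat$site0 + 1L]
      phi <- matrix(plogis(drop(dat$Xdet %*% st$alpha[, s])), dat$V, n,
                    byrow = TRUE)
      tot <- tot + sum(cpp_cells_loglik(dat$Yt[[s]], exp(eta), phi,
                                        plogis(st$lpsi[s]), spec$tail,
                                        spec$Kcap))
    }
    tot
  }

  st <- new_state()
  tries <- 0
  while (!is.finite(state_loglik(st))) {
    tries <- tries + 1
    if (tries > config$init_retries)
      stop("could not find a finite starting log-posterior after ",
           config$init_retries, " attempts")
    st <- new_state()
  }

  # columns of the abundance design that are site-constant indicators
  # (the intercept, treatment): these trade off against the site effects,
  # so joint recentering moves (gamma - d, beta_k + d) are added to break
  # the posterior ridge; the likelihood is invariant along them
  rc_cols <- list()
  if (n > 0) {
    for (k in seq_len(p)) {
      xk <- dat$Xab[, k]
      if (all(xk %in% c(0, 1))) {
        per_site <- tapply(xk, dat$site0, function(v) {
          if (all(v == v[1])) v[1] else NA_real_
        })
        if (!anyNA(per_site) && any(per_site == 1))
          rc_cols[[length(rc_cols) + 1]] <-
            list(k = k, sites = which(per_site == 1))
      }
    }
  }

  prop_b <- matrix(0.15, p, S); prop_a <- matrix(0.15, q, S)
  prop_p <- rep(0.6, S); prop_g <- rep(0.15, Tn)
  # intercept ridge: lambda * phi is far better identified than lambda and
  # phi separately, so a joint move shifts every species' abundance
  # intercept (and its hyper-mean) by +d and every detection intercept
  # (and hyper-mean) by -d, with a full likelihood evaluation
  i0 <- which(dat$ab_labels == "beta0")
  j0 <- which(dat$det_labels == "alpha0")
  use_ridge <- n > 0 && length(i0) == 1 && length(j0) == 1

  # Cholesky factors of (X'X/n)^-1 for block proposals aligned with the
  # design's collinearity structure
  chol_prop <- function(X) {
    G <- crossprod(X) / nrow(X)
    t(chol(solve(G + diag(1e-8, ncol(G)))))
  }
  if (n > 0) {
    Lb <- chol_prop(dat$Xab)
    La <- chol_prop(dat$Xdet)
    prop_blkb <- rep(0.3, S); prop_blka <- rep(0.3, S)
  } else {
    Lb <- diag(p); La <- diag(q)
    prop_blkb <- rep(0, S); prop_blka <- rep(0, S)
  }

  prop_sb <- rep(0.3, p); prop_sa <- rep(0.3, q); prop_ss <- 0.3
  prop_rc <- rep(0.2, length(rc_cols)); prop_ridge <- 0.1
  accB <- matrix(0, p, S); accA <- matrix(0, q, S)
  accP <- rep(0, S); accG <- rep(0, Tn)
  accSb <- rep(0, p); accSa <- rep(0, q); accSs <- 0
  accRc <- rep(0, length(rc_cols)); accRidge <- 0
  accBlkB <- rep(0, S); accBlkA <- rep(0, S)

  hyper_names <- c(paste0("mu_", dat$ab_labels),
                   paste0("sigma_", dat$ab_labels),
                   paste0("mu_", dat$det_labels),
                   paste0("sigma_", dat$det_labels), "sigma_site")
  sp_names <- c(
    as.vector(t(outer(dat$ab_labels, dat$species,
                      function(a, b) paste0(a, "[", b, "]")))),
    as.vector(t(outer(dat$det_labels, dat$species,
                      function(a, b) paste0(a, "[", b, "]")))),
    paste0("psi[", dat$species, "]"))
  par_names <- c(hyper_names, sp_names,
                 paste0("gamma[", dat$sites, "]"))
  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  kept <- matrix(NA_real_, n_keep, length(par_names),
                 dimnames = list(NULL, par_names))
  krow <- 0

  half_lp <- function(x) if (x < 0) -Inf else
    log(2) + dnorm(x, 0, hs, log = TRUE)

  for (it in seq_len(config$n_iter)) {
    if (n > 0) {
      sw <- cpp_mcmc_sweep(dat$Yt, dat$Xab, dat$Xdet, dat$site0, Tn,
                           st$beta, st$alpha, st$lpsi, st$gamma,
                           st$mu_b, st$sd_b, st$mu_a, st$sd_a,
                           st$sigma_site, prop_b, prop_a, prop_p, prop_g,
                           Lb, La, prop_blkb, prop_blka,
                           spec$tail, spec$Kcap)
      st$beta <- sw$beta; st$alpha <- sw$alpha
      st$lpsi <- sw$lpsi; st$gamma <- sw$gamma
      accB <- accB + sw$acc_beta; accA <- accA + sw$acc_alpha
      accP <- accP + sw$acc_psi; accG <- accG + sw$acc_gamma
      accBlkB <- accBlkB + sw$acc_blk_beta
      accBlkA <- accBlkA + sw$acc_blk_alpha
    } else {
      # prior-only: species-level conditionals are the priors themselves
      st$beta <- matrix(rnorm(p * S, st$mu_b, st$sd_b), p, S)
      st$alpha <- matrix(rnorm(q * S, st$mu_a, st$sd_a), q, S)
      st$lpsi <- qlogis(runif(S))
      st$gamma <- rnorm(Tn, 0, st$sigma_site)
    }

    if (use_ridge) {
      cur_ll <- sw$loglik
      d <- prop_ridge * rnorm(1)
      cand <- st
      cand$beta[i0, ] <- cand$beta[i0, ] + d
      cand$alpha[j0, ] <- cand$alpha[j0, ] - d
      new_ll <- state_loglik(cand)
      # species-level prior terms are invariant because the hyper-means
      # shift along; only the vague hyper-mean priors contribute
      ps <- 1 / sqrt(prior_prec)
      lr <- new_ll - cur_ll +
        dnorm(st$mu_b[i0] + d, 0, ps, log = TRUE) -
        dnorm(st$mu_b[i0], 0, ps, log = TRUE) +
        dnorm(st$mu_a[j0] - d, 0, ps, log = TRUE) -
        dnorm(st$mu_a[j0], 0, ps, log = TRUE)
      if (is.finite(lr) && log(runif(1)) < lr) {
        st <- cand
        st$mu_b[i0] <- st$mu_b[i0] + d
        st$mu_a[j0] <- st$mu_a[j0] - d
        accRidge <- accRidge + 1
      }
    }

    # likelihood-invariant recentering of site effects vs site-constant
    # coefficients: only the priors enter the acceptance ratio
    for (j in seq_along(rc_cols)) {
      k <- rc_cols[[j]]$k
      ts <- rc_cols[[j]]$sites
      d <- prop_rc[j] * rnorm(1)
      lr <- sum(dnorm(st$gamma[ts] - d, 0, st$sigma_site, log = TRUE) -
                  dnorm(st$gamma[ts], 0, st$sigma_site, log = TRUE)) +
        sum(dnorm(st$beta[k, ] + d, st$mu_b[k], st$sd_b[k], log = TRUE) -
              dnorm(st$beta[k, ], st$mu_b[k], st$sd_b[k], log = TRUE))
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$gamma[ts] <- st$gamma[ts] - d
        st$beta[k, ] <- st$beta[k, ] + d
        accRc[j] <- accRc[j] + 1
      }
    }

    # community hyper-means: conjugate Normal updates
    for (k in seq_len(p)) {
      prec <- prior_prec + S / st$sd_b[k]^2
      st$mu_b[k] <- rnorm(1, sum(st$beta[k, ]) / st$sd_b[k]^2 / prec,
                          sqrt(1 / prec))
    }
    for (k in seq_len(q)) {
      prec <- prior_prec + S / st$sd_a[k]^2
      st$mu_a[k] <- rnorm(1, sum(st$alpha[k, ]) / st$sd_a[k]^2 / prec,
                          sqrt(1 / prec))
    }

    # hyper standard deviations: random walk on the log scale
    for (k in seq_len(p)) {
      lsn <- log(st$sd_b[k]) + prop_sb[k] * rnorm(1)
      sn <- exp(lsn)
      lr <- sum(dnorm(st$beta[k, ], st$mu_b[k], sn, log = TRUE)) -
        sum(dnorm(st$beta[k, ], st$mu_b[k], st$sd_b[k], log = TRUE)) +
        half_lp(sn) - half_lp(st$sd_b[k]) + lsn - log(st$sd_b[k])
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$sd_b[k] <- sn; accSb[k] <- accSb[k] + 1
      }
    }
    for (k in seq_len(q)) {
      lsn <- log(st$sd_a[k]) + prop_sa[k] * rnorm(1)
      sn <- exp(lsn)
      lr <- sum(dnorm(st$alpha[k, ], st$mu_a[k], sn, log = TRUE)) -
        sum(dnorm(st$alpha[k, ], st$mu_a[k], st$sd_a[k], log = TRUE)) +
        half_lp(sn) - half_lp(st$sd_a[k]) + lsn - log(st$sd_a[k])
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$sd_a[k] <- sn; accSa[k] <- accSa[k] + 1
      }
    }
    {
      lsn <- log(st$sigma_site) + prop_ss * rnorm(1)
      sn <- exp(lsn)
      lr <- sum(dnorm(st$gamma, 0, sn, log = TRUE)) -
        sum(dnorm(st$gamma, 0, st$sigma_site, log = TRUE)) +
        half_lp(sn) - half_lp(st$sigma_site) + lsn - log(st$sigma_site)
      if (is.finite(lr) && log(runif(1)) < lr) {
        st$sigma_site <- sn; accSs <- accSs + 1
      }
    }

    # batch adaptation of proposal scales during burn-in
    if (it <= config$n_burnin && it %% config$adapt_interval == 0) {
      batch <- it %/% config$adapt_interval
      delta <- min(0.1, 1 / sqrt(batch))
      tune <- function(prop, acc)
        prop * exp(ifelse(acc / config$adapt_interval > 0.44, delta, -delta))
      prop_b <- tune(prop_b, accB); prop_a <- tune(prop_a, accA)
      prop_p <- tune(prop_p, accP); prop_g <- tune(prop_g, accG)
      prop_sb <- tune(prop_sb, accSb); prop_sa <- tune(prop_sa, accSa)
      prop_ss <- tune(prop_ss, accSs)
      if (length(rc_cols)) prop_rc <- tune(prop_rc, accRc)
      if (use_ridge) prop_ridge <- tune(prop_ridge, accRidge)
      tune_blk <- function(prop, acc)   # multivariate target ~0.25
        prop * exp(ifelse(acc / config$adapt_interval > 0.25, delta, -delta))
      if (n > 0) {
        prop_blkb <- tune_blk(prop_blkb, accBlkB)
        prop_blka <- tune_blk(prop_blka, accBlkA)
      }
      accB[] <- 0; accA[] <- 0; accP[] <- 0; accG[] <- 0
      accSb[] <- 0; accSa[] <- 0; accSs <- 0; accRc[] <- 0; accRidge <- 0
      accBlkB[] <- 0; accBlkA[] <- 0
    }

    if (it > config$n_burnin &&
        (it - config$n_burnin) %% config$thin == 0) {
      krow <- krow + 1
      kept[krow, ] <- c(st$mu_b, st$sd_b, st$mu_a, st$sd_a, st$sigma_site,
                        as.vector(t(st$beta)), as.vector(t(st$alpha)),
                        plogis(st$lpsi), st$gamma)
    }
    if (verbose && it %% 500 == 0)
      message("  iteration ", it, "/", config$n_iter)
  }
  kept
}

#' Fit a hierarchical community N-mixture model
#'
#' The workhorse of the package.  Fits the zero-inflated
#' Poisson-binomial N-mixture model with community-level hyperpriors to a
#' long-format repeated point-count table: species-level abundance and
#' detection coefficients are drawn from Normal hyperdistributions,
#' abundance has a shared site random effect, and each species carries a
#' zero-inflation probability.  The latent inclusion indicator and latent
#' abundance are marginalized exactly, and the posterior is explored by
#' an adaptive Metropolis-within-Gibbs sampler with multiple independent
#' chains.
#'
#' @param counts Long count table with columns `species`, `site`, `point`,
#'   `year`, `visit`, `count` (one row per survey per species).
#' @param covariates A `cnm_covariates` object; raw tables are
#'   standardized internally.
#' @param suites Optional named vector mapping species to suite labels
#'   (defaults to [default_suites()] entries for the species present).
#' @param spec A [model_spec()].
#' @param config An [mcmc_config()].
#' @param species Species pool when `counts` is empty (prior-only run).
#' @param verbose Print progress.
#' @return An object of class `comm_nmix` with components `draws` (a
#'   `cnm_draws` array: iterations x parameters x chains), `data`, `spec`,
#'   `config`, `suites`, `covariates` and `runtime`.  Methods: `print`,
#'   `summary`, `coef`, `plot`, `fitted`, `residuals`, `simulate`.
#' @examples
#' \donttest{
#' sim <- simulate_community(survey_design(
#'   n_sites = 4, points_per_site = 4, n_years = 1, visits_per_year = 3,
#'   suites = default_suites()[1:4]), seed = 7)
#' fit <- comm_nmix(sim$counts, sim$covariates,
#'                  config = mcmc_config(n_chains = 2, n_iter = 400,
#'                                       n_burnin = 200, thin = 2, seed = 7))
#' summary(fit)
#' }
#' @export
comm_nmix <- function(counts, covariates, suites = NULL,
                      spec = model_spec(), config = mcmc_config(),
                      species = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (!isTRUE(covariates$standardized))
    covariates <- prepare_covariates(covariates)
  if (is.null(counts) || nrow(counts) == 0) {
    if (is.null(species)) stop("species pool required for a prior-only run")
    dat <- empty_model_data(covariates, spec, species)
  } else {
    dat <- build_model_data(counts, covariates, spec)
  }
  if (is.null(suites)) {
    suites <- default_suites()
    suites <- suites[intersect(names(suites), dat$species)]
    if (length(suites) == 0) suites <- NULL
  }

  set.seed(config$seed)
  chain_seeds <- sample.int(2^31 - 2, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    if (verbose) message("chain ", ch, "/", config$n_chains)
    chains[[ch]] <- run_chain(dat, spec, config, chain_seeds[ch], verbose)
  }
  draws <- array(unlist(chains),
                 dim = c(nrow(chains[[1]]), ncol(chains[[1]]),
                         config$n_chains),
                 dimnames = list(NULL, colnames(chains[[1]]),
                                 paste0("chain", seq_len(config$n_chains))))
  class(draws) <- "cnm_draws"
  attr(draws, "config") <- config

  out <- list(draws = draws, data = dat, spec = spec, config = config,
              suites = suites, covariates = covariates, counts = counts,
              runtime = proc.time()[["elapsed"]] - t0,
              call = match.call())
  class(out) <- "comm_nmix"
  out
}

# zero-cell data skeleton for prior-only runs
empty_model_data <- function(covariates, spec, species) {
  pts0 <- covariates$points_z[0, , drop = FALSE]
  vis0 <- covariates$visits_z[0, , drop = FALSE]
  Xab <- stats::model.matrix(spec$abundance, pts0)
  Xdet <- stats::model.matrix(spec$detection, vis0)
  list(Yt = setNames(rep(list(matrix(0L, 1, 0)), length(species)), species),
       Xab = Xab, Xdet = Xdet, site0 = integer(0), sites = "S1",
       n = 0L, V = 1L, S = length(species), species = species,
       cells = covariates$points_z[0, c("point", "site", "year")],
       ab_labels = coef_labels(colnames(Xab), "beta"),
       det_labels = coef_labels(colnames(Xdet), "alpha"),
       constants = covariates$constants)
}

#' Sample the posterior of the community N-mixture model
#'
#' Thin wrapper over [comm_nmix()] returning only the retained posterior
#' draws.
#'
#' @inheritParams comm_nmix
#' @return A `cnm_draws` array (iterations x parameters x chains).
#' @export
run_mcmc <- function(counts, covariates, spec = model_spec(),
                     config = mcmc_config(), ...) {
  comm_nmix(counts, covariates, spec = spec, config = config, ...)$draws
}
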