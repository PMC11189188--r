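#' Specify the structure of the community N-mixture model
#'
#' Collects the abundance and detection model formulas, the prior
#' settings, and the marginalization truncation rule.  Fixed-effect
#' hyper-means get vague Normal(0, precision 0.001) priors; hyper
#' standard deviations and the site random-effect scale get half-Normal
#' priors with the given scale; zero-inflation probabilities get a
#' Beta(1, 1) prior per species.
#'
#' @param abundance Formula for the abundance covariates (evaluated on the
#'   standardized point x year table; `treatment` is the 0/1 flag).
#' @param detection Formula for the detection covariates (standardized
#'   visit table; `date2` is the squared standardized date).
#' @param prior_precision Prior precision of the Normal(0, .) priors on
#'   fixed-effect hyper-means.
#' @param hyper_sd_scale Scale of the half-Normal priors on hyper
#'   standard deviations and the site random-effect scale.
#' @param tail Poisson upper-tail mass bounding the abundance truncation
#'   limit K (the sum is further extended until additional terms are
#'   relatively negligible).
#' @param Kcap Hard cap on the truncation limit.
#' @return An object of class `cnm_spec`.
#' @export
model_spec <- function(abundance = ~ grass + woody + vor2 + basal + treatment,
                       detection = ~ date + date2 + wind + disturbance,
                       prior_precision = 0.001, hyper_sd_scale = 2,
                       tail = 1e-12, Kcap = 300) {
  stopifnot(inherits(abundance, "formula"), inherits(detection, "formula"),
            prior_precision > 0, hyper_sd_scale > 0, tail > 0, Kcap >= 1)
  structure(list(abundance = abundance, detection = detection,
                 prior_precision = prior_precision,
                 hyper_sd_scale = hyper_sd_scale,
                 tail = tail, Kcap = as.integer(Kcap)),
            class = "cnm_spec")
}

#' Expected abundance from the log-linear abundance model
#'
#' `lambda = exp(beta0 + beta' x + gamma)`.
#'
#' @param beta0 Species intercept.
#' @param beta Coefficient vector.
#' @param x Covariate vector conforming to `beta`.
#' @param gamma Site random effect (default 0).
#' @return Expected abundance (birds per plot), strictly positive.
#' @export
linear_abundance <- function(beta0, beta = numeric(0), x = numeric(0),
                             gamma = 0) {
  if (length(beta) != length(x))
    stop("beta and x must conform")
  lambda <- exp(beta0 + sum(beta * x) + gamma)
  if (!is.finite(lambda))
    stop("non-finite expected abundance")
  lambda
}

#' Per-visit detection probability from the logit-linear detection model
#'
#' `phi = plogis(alpha0 + alpha' v)`, strictly inside (0, 1) for finite
#' predictors.
#'
#' @param alpha0 Species detection intercept.
#' @param alpha Coefficient vector.
#' @param v Visit covariate vector conforming to `alpha`.
#' @return Detection probability.
#' @export
linear_detection <- function(alpha0, alpha = numeric(0), v = numeric(0)) {
  if (length(alpha) != length(v))
    stop("alpha and v must conform")
  plogis(alpha0 + sum(alpha * v))
}

#' Exactly marginalized likelihood of one species x point x year cell
#'
#' Computes `log[(1 - psi) 1{all y = 0} +
#' psi * sum_M Pois(M; lambda) prod_v Binom(y_v; M, phi_v)]`, summing the
#' latent inclusion indicator and latent abundance out exactly.  The sum
#' runs from `max(y)` to an adaptive truncation limit (smallest K with
#' Poisson tail mass below `tail`, extended until terms are relatively
#' negligible, capped at `Kcap`), or to a forced `K` if supplied.
#'
#' @param y Integer vector of per-visit counts.
#' @param psi Inclusion (zero-inflation) probability in \[0, 1\].
#' @param lambda Expected abundance, > 0.
#' @param phi Per-visit detection probabilities (recycled to `length(y)`).
#' @param K Optional forced truncation limit, must be >= `max(y)`.
#' @param tail,Kcap Truncation rule, see [model_spec()].
#' @return Log-likelihood contribution (may be `-Inf`).
#' @export
cell_marginal_loglik <- function(y, psi, lambda, phi, K = NULL,
                                 tail = 1e-12, Kcap = 300) {
  if (any(y < 0) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]")
  if (!is.finite(lambda) || lambda <= 0)
    stop("lambda must be finite and positive")
  phi <- rep_len(phi, length(y))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (!is.null(K)) {
    if (K < max(y)) stop("K must be at least max(y)")
    Kforce <- as.integer(K)
  } else Kforce <- -1L
  cpp_cell_loglik(as.integer(y), lambda, as.numeric(phi), psi,
                  tail, as.integer(Kcap), Kforce)
}

#' Plain (non-inflated) N-mixture cell log-likelihood
#'
#' Standard N-mixture marginal for a single cell,
#' `log sum_M Pois(M; lambda) prod_v Binom(y_v; M, phi_v)`, computed by a
#' direct vectorized summation.  With `psi = 1` the zero-inflated
#' marginal reduces to this quantity exactly.
#'
#' @inheritParams cell_marginal_loglik
#' @return Log-likelihood contribution.
#' @export
nmix_cell_loglik <- function(y, lambda, phi) {
  phi <- rep_len(phi, length(y))
  maxy <- max(y)
  K <- max(maxy, ceiling(lambda + 12 * sqrt(lambda + 1)) + 30)
  M <- maxy:K
  lt <- dpois(M, lambda, log = TRUE)
  for (v in seq_along(y))
    lt <- lt + dbinom(y[v], M, phi[v], log = TRUE)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

# normalize model.matrix column names to coefficient labels
coef_labels <- function(cols, prefix) {
  ifelse(cols == "(Intercept)", paste0(prefix, "0"),
         paste0(prefix, "_", gsub("[^A-Za-z0-9_.]", ".", cols)))
}

# Assemble per-species count matrices and design matrices aligned on the
# point x year cell grid.  Counts must be balanced (every species x cell
# x visit exactly once).
build_model_data <- function(counts, covariates, spec) {
  if (!isTRUE(covariates$standardized))
    covariates <- prepare_covariates(covariates)
  pts <- covariates$points_z
  vis <- covariates$visits_z
  n <- nrow(pts)
  cell_key <- paste(pts$point, pts$year)
  species <- sort(unique(counts$species))
  S <- length(species)
  visits <- sort(unique(counts$visit))
  V <- length(visits)

  key <- paste(counts$species, counts$point, counts$year, counts$visit)
  if (anyDuplicated(key))
    stop("duplicated species x point x year x visit rows in counts")
  if (nrow(counts) != S * n * V)
    stop("counts are not balanced over species x cell x visit")

  Yt <- vector("list", S)
  names(Yt) <- species
  for (s in seq_len(S)) {
    sub <- counts[counts$species == species[s], ]
    m <- matrix(NA_integer_, V, n)
    idx <- match(paste(sub$point, sub$year), cell_key)
    if (anyNA(idx)) stop("counts reference cells absent from covariates")
    m[cbind(match(sub$visit, visits), idx)] <- as.integer(sub$count)
    if (anyNA(m)) stop("missing survey rows for species ", species[s])
    if (any(m < 0)) stop("negative counts for species ", species[s])
    Yt[[s]] <- m
  }

  Xab <- stats::model.matrix(spec$abundance, pts)
  vkey <- paste(vis$point, vis$year, vis$visit)
  want <- paste(rep(cell_key, V), rep(visits, each = n))
  ord <- match(want, paste(paste(vis$point, vis$year), vis$visit))
  if (anyNA(ord)) stop("visit covariates missing for some surveys")
  Xdet <- stats::model.matrix(spec$detection, vis[ord, , drop = FALSE])

  sites <- sort(unique(pts$site))
  site0 <- match(pts$site, sites) - 1L

  list(Yt = Yt, Xab = Xab, Xdet = Xdet, site0 = site0, sites = sites,
       n = n, V = V, S = S, species = species,
       cells = pts[, c("point", "site", "year")],
       ab_labels = coef_labels(colnames(Xab), "beta"),
       det_labels = coef_labels(colnames(Xdet), "alpha"),
       constants = covariates$constants)
}

#' Total marginal log-likelihood of a community dataset
#'
#' Sum of the exactly marginalized cell contributions over all species x
#' point x year cells, at the given species-level parameters.
#'
#' @param counts Long count table (`species`, `site`, `point`, `year`,
#'   `visit`, `count`); an empty table gives 0.
#' @param covariates A `cnm_covariates` object.
#' @param params A `cnm_params` list (see [draw_species_params()]); its
#'   coefficient names must match the model formulas.
#' @param spec A [model_spec()].
#' @return Scalar log-likelihood.
#' @export
total_loglik <- function(counts, covariates, params, spec = model_spec()) {
  if (nrow(counts) == 0) return(0)
  dat <- build_model_data(counts, covariates, spec)
  ab_cols <- setdiff(colnames(dat$Xab), "(Intercept)")
  det_cols <- setdiff(colnames(dat$Xdet), "(Intercept)")
  if (!all(ab_cols %in% colnames(params$beta)))
    stop("params$beta lacks columns: ",
         paste(setdiff(ab_cols, colnames(params$beta)), collapse = ", "))
  total <- 0
  for (s in seq_len(dat$S)) {
    sp <- dat$species[s]
    eta <- params$beta0[[sp]] +
      drop(dat$Xab[, ab_cols, drop = FALSE] %*% params$beta[sp, ab_cols]) +
      params$gamma[match(dat$cells$site, dat$sites)]
    eta_det <- params$alpha0[[sp]] +
      drop(dat$Xdet[, det_cols, drop = FALSE] %*% params$alpha[sp, det_cols])
    if (any(!is.finite(eta)) || any(!is.finite(eta_det)))
      stop("non-finite linear predictor for species ", sp)
    phi <- matrix(plogis(eta_det), dat$V, dat$n, byrow = TRUE)
    ll <- cpp_cells_loglik(dat$Yt[[s]], exp(eta), phi, params$psi[[sp]],
                           spec$tail, spec$Kcap)
    if (any(is.nan(ll)))
      stop("likelihood failed for species ", sp, " at cell ",
           which(is.nan(ll))[1])
    total <- total + sum(ll)
  }
  total
}

half_normal_logpdf <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

#' Joint log-prior of species parameters and community hyperparameters
#'
#' Vague Normal(0, precision `prior_precision`) on every fixed-effect
#' hyper-mean; half-Normal(`hyper_sd_scale`) on every hyper standard
#' deviation and the site random-effect scale; species-level Normal
#' densities around their hyper-means; Beta(1, 1) on each zero-inflation
#' probability; Normal(0, `sigma_site`) on each site effect.
#'
#' @param params A `cnm_params` list.
#' @param hyper A [community_hyperparams()].
#' @param spec A [model_spec()].
#' @return Scalar log-prior density; `-Inf` if any scale is negative or
#'   any psi falls outside \[0, 1\].
#' @export
log_prior <- function(params, hyper, spec = model_spec()) {
  sds <- c(hyper$sigma_beta0, hyper$sigma_beta, hyper$sigma_alpha0,
           hyper$sigma_alpha, hyper$sigma_site)
  if (any(sds < 0)) return(-Inf)
  if (any(params$psi < 0 | params$psi > 1)) return(-Inf)
  prior_sd <- 1 / sqrt(spec$prior_precision)
  lp <- sum(dnorm(c(hyper$mu_beta0, hyper$mu_beta, hyper$mu_alpha0,
                    hyper$mu_alpha), 0, prior_sd, log = TRUE))
  lp <- lp + sum(half_normal_logpdf(sds, spec$hyper_sd_scale))
  lp <- lp + sum(dnorm(params$beta0, hyper$mu_beta0, hyper$sigma_beta0,
                       log = TRUE))
  for (k in seq_along(hyper$mu_beta))
    lp <- lp + sum(dnorm(params$beta[, k], hyper$mu_beta[k],
                         hyper$sigma_beta[k], log = TRUE))
  lp <- lp + sum(dnorm(params$alpha0, hyper$mu_alpha0, hyper$sigma_alpha0,
                       log = TRUE))
  for (k in seq_along(hyper$mu_alpha))
    lp <- lp + sum(dnorm(params$alpha[, k], hyper$mu_alpha[k],
                         hyper$sigma_alpha[k], log = TRUE))
  # Beta(1, 1) on psi contributes 0
  lp + sum(dnorm(params$gamma, 0, hyper$sigma_site, log = TRUE))
}
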