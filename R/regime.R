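#' Vegetation and detection covariate regimes by treatment group
#'
#' Describes, per treatment group, the truncated-normal distribution
#' (mean, sd, lower, upper) from which each point-level vegetation
#' covariate is drawn, plus the supports of the visit-level detection
#' covariates.  The defaults reproduce the reference study's observed
#' covariate summaries: grass and woody groundcover (%), horizontal visual
#' obstruction at 2 m (VOR2, %), and live-tree basal area (m2/ha), with
#' treatment points carrying more grass and markedly less woody cover,
#' visual obstruction and basal area than unmanaged controls.
#'
#' Visit dates are drawn uniformly over a 16 May - 10 Aug season expressed
#' as day-of-season 0-86; wind speed uniformly on 0-15 km/h (surveys were
#' not run above that); disturbance on the integer scale 0-4.
#'
#' @param abundance A data frame with columns `covariate`, `group`,
#'   `mean`, `sd`, `lower`, `upper`.  Default: the reference regimes.
#' @param date_range,wind_range Numeric length-2 supports for visit date
#'   (day of season) and wind speed.
#' @param disturbance_levels Integer support for the disturbance score.
#' @return An object of class `cnm_regime`.
#' @export
covariate_regime <- function(abundance = default_abundance_regime(),
                             date_range = c(0, 86),
                             wind_range = c(0, 15),
                             disturbance_levels = 0:4) {
  req <- c("covariate", "group", "mean", "sd", "lower", "upper")
  if (!all(req %in% names(abundance)))
    stop("abundance regime needs columns: ", paste(req, collapse = ", "))
  bad <- abundance$sd < 0 | abundance$lower > abundance$upper
  if (any(bad))
    stop("invalid regime rows for: ",
         paste(unique(abundance$covariate[bad]), collapse = ", "))
  infeasible <- abundance$mean < abundance$lower | abundance$mean > abundance$upper
  if (any(infeasible))
    stop("infeasible regime (mean outside [lower, upper]) for covariate(s): ",
         paste(unique(abundance$covariate[infeasible]), collapse = ", "))
  stopifnot(length(date_range) == 2, length(wind_range) == 2,
            date_range[1] <= date_range[2], wind_range[1] <= wind_range[2])
  out <- list(abundance = abundance, date_range = date_range,
              wind_range = wind_range,
              disturbance_levels = as.integer(disturbance_levels))
  class(out) <- "cnm_regime"
  out
}

#' Reference vegetation regimes (treatment vs control)
#'
#' Mean, standard deviation and observed range per covariate and group.
#' Percent covariates live on \[0, 100\]; basal area on m2/ha.
#'
#' @return Data frame usable as the `abundance` argument of
#'   [covariate_regime()].
#' @export
default_abundance_regime <- function() {
  data.frame(
    covariate = rep(c("grass", "woody", "vor2", "basal"), each = 2),
    group = rep(c("control", "treatment"), 4),
    mean  = c(0.28, 12.69, 48.76, 32.55, 47.66, 36.56, 28.89, 9.45),
    sd    = c(1.64, 24.49, 40.48, 34.33, 27.40, 32.67, 9.83, 8.04),
    lower = c(0, 0, 0, 0, 0, 0, 3.44, 0),
    upper = c(15, 100, 100, 100, 100, 100, 65.04, 34.05),
    stringsAsFactors = FALSE)
}

#' Community-level hyperparameters for the hierarchical model
#'
#' Species-level regression coefficients are drawn from Normal
#' hyperdistributions: `beta0_i ~ N(mu_beta0, sigma_beta0^2)` and so on
#' for each abundance and detection covariate.  Site random effects are
#' `N(0, sigma_site^2)`.  Zero-inflation inclusion probabilities `psi_i`
#' are either fixed (scalar or per-species vector) or drawn from a
#' Beta(shape1, shape2) hyperprior when `psi` has length 2 and
#' `psi_beta = TRUE`.
#'
#' Defaults give a community of moderately common species (median
#' expected abundance ~1.5 birds per plot), detection around 0.18 at mean
#' conditions, a strong negative basal-area effect, and psi = 0.6.
#'
#' @param mu_beta0,sigma_beta0 Abundance intercept hyper-mean and sd.
#' @param mu_beta Named numeric vector of abundance covariate hyper-means.
#' @param sigma_beta Hyper-sd(s) for abundance covariates (recycled).
#' @param mu_alpha0,sigma_alpha0 Detection intercept hyper-mean and sd.
#' @param mu_alpha Named numeric vector of detection covariate hyper-means.
#' @param sigma_alpha Hyper-sd(s) for detection covariates (recycled).
#' @param psi Zero-inflation probability: scalar, per-species vector, or
#'   (with `psi_beta = TRUE`) Beta shape parameters of length 2.
#' @param psi_beta Interpret length-2 `psi` as Beta shapes.
#' @param sigma_site Site random-effect scale.
#' @return An object of class `cnm_hyper`.
#' @export
community_hyperparams <- function(
    mu_beta0 = 0.4, sigma_beta0 = 0.5,
    mu_beta = c(grass = 0.05, woody = -0.15, vor2 = -0.1, basal = -0.4,
                treatment = 0.45),
    sigma_beta = 0.3,
    mu_alpha0 = -1.5, sigma_alpha0 = 0.5,
    mu_alpha = c(date = -0.4, date2 = -0.2, wind = -0.15, disturbance = 0),
    sigma_alpha = 0.2,
    psi = 0.6, psi_beta = FALSE,
    sigma_site = 0.25) {
  sigma_beta <- rep_len(sigma_beta, length(mu_beta))
  sigma_alpha <- rep_len(sigma_alpha, length(mu_alpha))
  stopifnot(sigma_beta0 >= 0, all(sigma_beta >= 0), sigma_alpha0 >= 0,
            all(sigma_alpha >= 0), sigma_site >= 0)
  if (psi_beta) {
    stopifnot(length(psi) == 2, all(psi > 0))
  } else if (any(psi < 0 | psi > 1)) {
    stop("zero-inflation probabilities must lie in [0, 1]")
  }
  out <- list(mu_beta0 = mu_beta0, sigma_beta0 = sigma_beta0,
              mu_beta = mu_beta, sigma_beta = sigma_beta,
              mu_alpha0 = mu_alpha0, sigma_alpha0 = sigma_alpha0,
              mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
              psi = psi, psi_beta = psi_beta, sigma_site = sigma_site)
  class(out) <- "cnm_hyper"
  out
}
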