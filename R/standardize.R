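#' Standardize a numeric covariate
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (divisor
#' n - 1), keeping the constants so the transformation can be inverted
#' exactly.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return List of class `cnm_std` with `values` (standardized), `center`
#'   and `scale`.
#' @seealso [unstandardize()]
#' @export
standardize <- function(values) {
  if (length(values) < 2)
    stop("standardization needs at least two values")
  m <- mean(values)
  s <- sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant covariate (sd = 0)")
  structure(list(values = (values - m) / s, center = m, scale = s),
            class = "cnm_std")
}

#' Invert a standardization
#'
#' @param std A `cnm_std` object (or list with `center`/`scale`).
#' @param values Standardized values; defaults to those stored in `std`.
#' @return Values on the original scale.
#' @export
unstandardize <- function(std, values = std$values) {
  values * std$scale + std$center
}

#' Standardize the covariates entering the model
#'
#' Produces standardized companions of the point-level vegetation
#' covariates and visit-level detection covariates (pooled over treatment
#' groups and years, one population per covariate), converts the treatment
#' flag to 0/1, and adds the squared standardized date (`date2`).  The
#' standardization constants are stored for back-transformation.
#'
#' @param covariates A `cnm_covariates` object with raw `points` and
#'   `visits` tables.
#' @param abundance_vars Point-level covariates to standardize.
#' @param detection_vars Visit-level covariates to standardize.
#' @return The input object with added `points_z`, `visits_z` (standardized
#'   design tables) and `constants` (covariate, center, scale), and
#'   `standardized = TRUE`.
#' @export
prepare_covariates <- function(covariates,
                               abundance_vars = intersect(
                                 c("grass", "woody", "vor2", "basal"),
                                 names(covariates$points)),
                               detection_vars = c("date", "wind", "disturbance")) {
  stopifnot(inherits(covariates, "cnm_covariates"))
  pts <- covariates$points
  vis <- covariates$visits

  drop_p <- !complete.cases(pts[, c("point", "year", abundance_vars)])
  drop_v <- !complete.cases(vis[, c("point", "year", "visit", detection_vars)])
  if (any(drop_p) || any(drop_v)) {
    message(sum(drop_p), " point-level and ", sum(drop_v),
            " visit-level records dropped for missing covariates")
    pts <- pts[!drop_p, , drop = FALSE]
    vis <- vis[!drop_v, , drop = FALSE]
  }

  constants <- data.frame(covariate = character(0), center = numeric(0),
                          scale = numeric(0), stringsAsFactors = FALSE)
  points_z <- pts[, c("point", "site", "year")]
  points_z$treatment <- as.numeric(pts$treatment == "treatment")
  for (cv in abundance_vars) {
    st <- standardize(pts[[cv]])
    points_z[[cv]] <- st$values
    constants <- rbind(constants, data.frame(covariate = cv,
                                             center = st$center,
                                             scale = st$scale))
  }
  visits_z <- vis[, c("point", "year", "visit")]
  for (cv in detection_vars) {
    st <- standardize(vis[[cv]])
    visits_z[[cv]] <- st$values
    constants <- rbind(constants, data.frame(covariate = cv,
                                             center = st$center,
                                             scale = st$scale))
  }
  # quadratic season term on the standardized date (not re-standardized)
  if ("date" %in% detection_vars) visits_z$date2 <- visits_z$date^2

  covariates$points_z <- points_z
  covariates$visits_z <- visits_z
  covariates$constants <- constants
  covariates$standardized <- TRUE
  covariates
}
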