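#' Default species pool: 12 BCR 30 priority species in three habitat suites
#'
#' Six Forested Upland species, five Scrub-Shrub species and one Grassland
#' species, keyed by their standard four-letter banding codes.
#'
#' @return Named character vector mapping species code to suite label.
#' @export
default_suites <- function() {
  c(BAOR = "Forested Upland", BAWW = "Forested Upland",
    GCFL = "Forested Upland", NOFL = "Forested Upland",
    SCTA = "Forested Upland", WOTH = "Forested Upland",
    BWWA = "Scrub-Shrub", BRTH = "Scrub-Shrub", EATO = "Scrub-Shrub",
    FISP = "Scrub-Shrub", PRAW = "Scrub-Shrub",
    EAKI = "Grassland")
}

#' Define a repeated point-count survey design
#'
#' Describes the sampling frame for a multi-species repeated point-count
#' study: sites holding survey points, half assigned to a treatment
#' (actively managed) arm and half to a control arm, visited several times
#' per survey year.  The default reproduces the reference design of 150
#' points across 18 sites (75 treatment / 75 control), 3 visits per year
#' over 4 survey years, for 12 species in 3 habitat suites.
#'
#' @param n_sites Number of survey sites.
#' @param points_per_site Points per site; scalar or length-`n_sites`
#'   vector.  The default splits 150 points over 18 sites so each
#'   treatment arm holds exactly 75 points.
#' @param n_years Number of survey years.
#' @param visits_per_year Repeat visits per point per year.
#' @param suites Named character vector mapping species codes to suite
#'   labels (`"Forested Upland"`, `"Scrub-Shrub"`, `"Grassland"`).
#' @param treatment Character vector of `"treatment"`/`"control"` labels,
#'   one per site.  Defaults to the first half treatment, second half
#'   control.
#'
#' @return An object of class `cnm_design`: a list with the design
#'   dimensions, the per-site point counts, per-point site and treatment
#'   lookups, and the suite map.
#' @examples
#' d <- survey_design()
#' d$n_points            # 150
#' d$n_surveys           # 150 * 4 * 3 = 1800
#' @export
survey_design <- function(n_sites = 18,
                          points_per_site = rep(c(9, 9, 9, 8, 8, 8, 8, 8, 8), 2),
                          n_years = 4, visits_per_year = 3,
                          suites = default_suites(),
                          treatment = rep(c("treatment", "control"),
                                          each = ceiling(n_sites / 2))[seq_len(n_sites)]) {
  if (length(points_per_site) == 1L)
    points_per_site <- rep(points_per_site, n_sites)
  stopifnot(n_sites >= 1, n_years >= 1, visits_per_year >= 1,
            length(points_per_site) == n_sites, all(points_per_site >= 1),
            length(treatment) == n_sites,
            all(treatment %in% c("treatment", "control")))
  if (is.null(names(suites)) || anyDuplicated(names(suites)))
    stop("'suites' must be a named vector with unique species codes")
  n_points <- sum(points_per_site)
  point_site <- rep(seq_len(n_sites), points_per_site)
  out <- list(
    n_sites = as.integer(n_sites),
    points_per_site = as.integer(points_per_site),
    n_points = as.integer(n_points),
    n_years = as.integer(n_years),
    visits_per_year = as.integer(visits_per_year),
    n_species = length(suites),
    species = names(suites),
    suites = suites,
    treatment = treatment,
    point_site = point_site,
    point_treatment = treatment[point_site],
    n_surveys = as.integer(n_points * n_years * visits_per_year))
  class(out) <- "cnm_design"
  out
}

#' @export
print.cnm_design <- function(x, ...) {
  cat("Point-count survey design\n")
  cat(sprintf("  %d points in %d sites (%d treatment / %d control points)\n",
              x$n_points, x$n_sites,
              sum(x$point_treatment == "treatment"),
              sum(x$point_treatment == "control")))
  cat(sprintf("  %d year(s) x %d visit(s): %d point-count surveys\n",
              x$n_years, x$visits_per_year, x$n_surveys))
  cat(sprintf("  %d species in %d suite(s)\n",
              x$n_species, length(unique(x$suites))))
  invisible(x)
}
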