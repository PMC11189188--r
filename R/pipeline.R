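#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (or read) -> covariate prep (standardization,
#' collinearity screen, treatment/control comparison) -> fit -> summarize
#' -> derived quantities, writing every table as plain delimited text
#' plus a run manifest.  The whole run is deterministic under the
#' configured seed, and every output file carries the hash of the
#' normalized configuration that produced it.
#'
#' Configuration (YAML file or list): `seed`; `mode` ("simulate" or
#' "analyze"); for simulation a `design` block (n_sites,
#' points_per_site, n_years, visits_per_year, suites map) and optional
#' `hyper` overrides for [community_hyperparams()]; for analysis a
#' `paths` block (counts, covariates_points, covariates_visits) and a
#' `suites` map; optional `model` (abundance/detection formulas, tail,
#' Kcap) and `mcmc` ([mcmc_config()] fields) blocks.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param out Output directory (overrides `config$out`).
#' @return Invisibly, a list with the fit and all derived tables plus the
#'   output directory.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out)) out <- config$out
  if (is.null(out)) stop("no output directory configured")
  seed <- config$seed
  if (is.null(seed)) stop("config must set a seed")
  mode <- if (is.null(config$mode)) "simulate" else config$mode

  # validate before any compute: the suite map must be resolvable
  suites <- NULL
  if (mode == "simulate") {
    if (is.null(config$design$suites))
      stop("config missing suite map (design$suites)")
    suites <- unlist(config$design$suites)
  } else if (mode == "analyze") {
    if (is.null(config$suites))
      stop("config missing suite map (suites)")
    suites <- unlist(config$suites)
    for (p in c("counts", "covariates_points", "covariates_visits"))
      if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]]))
        stop("configured file missing: ", p)
  } else stop("mode must be 'simulate' or 'analyze'")

  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  norm_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config, norm_path)
  config_hash <- unname(tools::md5sum(norm_path))

  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    message(sprintf("[%s] done in %.2fs", name, timings[[name]]))
    res
  }

  if (mode == "simulate") {
    sim <- stage("simulate", {
      dn <- config$design
      design <- survey_design(
        n_sites = dn$n_sites %||% 18,
        points_per_site = dn$points_per_site %||%
          rep(c(9, 9, 9, 8, 8, 8, 8, 8, 8), 2),
        n_years = dn$n_years %||% 4,
        visits_per_year = dn$visits_per_year %||% 3,
        suites = suites)
      hy <- do.call(community_hyperparams, make_hyper_args(config$hyper))
      simulate_community(design, covariate_regime(), hy, seed = seed)
    })
    counts <- sim$counts
    covariates <- sim$covariates
  } else {
    loaded <- stage("read", {
      list(counts = read_counts(config$paths$counts),
           covariates = read_covariates(config$paths$covariates_points,
                                        config$paths$covariates_visits))
    })
    counts <- loaded$counts
    covariates <- loaded$covariates
  }

  prep <- stage("prep", {
    cov <- if (isTRUE(covariates$standardized)) covariates else
      prepare_covariates(covariates)
    scr <- correlation_screen(cov)
    cmp <- compare_treatment_groups(cov)
    list(cov = cov, screen = scr, compare = cmp)
  })

  fit <- stage("fit", {
    mc <- config$mcmc
    cfg <- mcmc_config(n_chains = mc$n_chains %||% 3,
                       n_iter = mc$n_iter %||% 4000,
                       n_burnin = mc$n_burnin %||% 1500,
                       thin = mc$thin %||% 5,
                       seed = seed)
    md <- config$model
    spec <- model_spec(
      abundance = if (is.null(md$abundance)) model_spec()$abundance else
        stats::as.formula(md$abundance),
      detection = if (is.null(md$detection)) model_spec()$detection else
        stats::as.formula(md$detection),
      tail = md$tail %||% 1e-12, Kcap = md$Kcap %||% 300)
    comm_nmix(counts, prep$cov, suites = suites, spec = spec, config = cfg)
  })

  derived <- stage("derive", {
    zm <- build_z_matrix(fit, seed = seed)
    list(summary = summary(fit),
         suite = suite_summary(fit),
         detection = detection_summary(fit),
         zero_inflation = zero_inflation_summary(fit),
         jaccard = jaccard_posterior(zm))
  })

  stage("write", {
    write_counts(counts, file.path(out, "counts.tsv"), config_hash)
    write_covariates(covariates, file.path(out, "covariates_points.tsv"),
                     file.path(out, "covariates_visits.tsv"), config_hash)
    write_tsv(prep$screen$excluded, file.path(out, "screen_excluded.tsv"),
              config_hash)
    write_tsv(data.frame(retained = prep$screen$retained),
              file.path(out, "screen_retained.tsv"), config_hash)
    write_tsv(prep$compare, file.path(out, "group_comparison.tsv"),
              config_hash)
    write_tsv(derived$summary, file.path(out, "summary.tsv"), config_hash)
    write_tsv(derived$suite, file.path(out, "suite_summary.tsv"), config_hash)
    write_tsv(derived$detection, file.path(out, "detection.tsv"), config_hash)
    write_tsv(derived$zero_inflation, file.path(out, "zero_inflation.tsv"),
              config_hash)
    write_tsv(derived$jaccard, file.path(out, "jaccard.tsv"), config_hash)
    write_draws(fit$draws, file.path(out, "draws.tsv"), config_hash)
    manifest <- list(
      config_hash = config_hash, seed = seed, mode = mode,
      package_version = as.character(utils::packageVersion("commNmix")),
      r_version = R.version.string,
      n_species = fit$data$S, n_cells = fit$data$n, n_visits = fit$data$V,
      n_count_rows = nrow(counts),
      excluded_covariates = prep$screen$excluded$covariate,
      timings = as.list(timings))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    NULL
  })

  invisible(list(out = out, fit = fit, screen = prep$screen,
                 compare = prep$compare, derived = derived,
                 config_hash = config_hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# translate a YAML hyper block into community_hyperparams() arguments
make_hyper_args <- function(hy) {
  if (is.null(hy)) return(list())
  args <- hy
  for (nm in c("mu_beta", "mu_alpha"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  args
}
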