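summ_ci <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), lower = unname(quantile(x, 0.025)),
    upper = unname(quantile(x, 0.975)))
}

check_suites <- function(fit) {
  suites <- fit$suites
  if (is.null(suites)) stop("fit carries no suite map")
  miss <- setdiff(fit$data$species, names(suites))
  if (length(miss))
    stop("missing suite assignment for: ", paste(miss, collapse = ", "))
  suites[fit$data$species]
}

# species-level draw matrix -> species/suite/community summary table
aggregate_species_draws <- function(mat, suites, quantity) {
  species <- colnames(mat)
  rows <- list()
  for (sp in species)
    rows[[length(rows) + 1]] <- data.frame(
      level = "species", name = sp, t(summ_ci(mat[, sp])),
      stringsAsFactors = FALSE)
  for (su in unique(suites)) {
    member <- species[suites == su]
    if (length(member) == 0) stop("empty suite: ", su)
    sm <- rowMeans(mat[, member, drop = FALSE])
    rows[[length(rows) + 1]] <- data.frame(
      level = "suite", name = su, t(summ_ci(sm)), stringsAsFactors = FALSE)
  }
  cm <- rowMeans(mat)
  rows[[length(rows) + 1]] <- data.frame(
    level = "community", name = "community", t(summ_ci(cm)),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$quantity <- quantity
  out[, c("quantity", "level", "name", "mean", "lower", "upper")]
}

#' Posterior detection probability by species, suite and community
#'
#' Per posterior draw, species-level detection probability is the
#' inverse-logit detection intercept (detection at mean covariate
#' conditions, since detection covariates are centered); suite and
#' community values are unweighted means over member species within the
#' same draw, so the summaries propagate full posterior uncertainty.
#'
#' @param fit A `comm_nmix` fit with a suite map.
#' @return Data frame with `quantity = "P_d"` rows per species, suite and
#'   community: posterior mean and 95% CrI.
#' @export
detection_summary <- function(fit) {
  suites <- check_suites(fit)
  a0 <- pooled_draws(fit, paste0("alpha0[", fit$data$species, "]"))
  pd <- plogis(a0)
  colnames(pd) <- fit$data$species
  aggregate_species_draws(pd, suites, "P_d")
}

#' Posterior zero-inflation rate by species, suite and community
#'
#' Same aggregation as [detection_summary()], over the per-species
#' inclusion probabilities psi.
#'
#' @param fit A `comm_nmix` fit with a suite map.
#' @return Data frame with `quantity = "phi_zi"` rows.
#' @export
zero_inflation_summary <- function(fit) {
  suites <- check_suites(fit)
  ps <- pooled_draws(fit, paste0("psi[", fit$data$species, "]"))
  colnames(ps) <- fit$data$species
  aggregate_species_draws(ps, suites, "phi_zi")
}

#' Posterior presence-absence (z) matrix
#'
#' For each posterior draw and each species x point, `z = 1` iff the
#' latent abundance is positive in at least one year at that point.
#' Points where the species was ever counted get `z = 1` deterministically;
#' for all-zero cells the latent state is drawn from its conditional
#' distribution given the parameters and the zero counts:
#' `P(M > 0 | y = 0) = psi (e^{-lambda(1-q)} - e^{-lambda}) /
#' ((1 - psi) + psi e^{-lambda(1-q)})` with `q` the product of per-visit
#' miss probabilities.
#'
#' @param fit A `comm_nmix` fit.
#' @param n_draws Number of posterior draws to use (default: all, capped
#'   at 1000).
#' @param seed Optional seed for the latent-state draws.
#' @return A `cnm_zmatrix`: integer array draws x species x points with
#'   dimnames.
#' @export
build_z_matrix <- function(fit, n_draws = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- fit$data
  pd <- pooled_draws(fit)
  total <- nrow(pd)
  if (is.null(n_draws)) n_draws <- min(total, 1000)
  use <- if (n_draws >= total) seq_len(total) else
    sort(sample.int(total, n_draws))
  points <- sort(unique(dat$cells$point))
  P <- length(points)
  cell_point <- match(dat$cells$point, points)

  z <- array(0L, dim = c(length(use), dat$S, P),
             dimnames = list(NULL, dat$species, paste0("p", points)))
  for (s in seq_len(dat$S)) {
    sp <- dat$species[s]
    ever_seen_cell <- colSums(dat$Yt[[s]]) > 0
    seen_point <- tapply(ever_seen_cell, cell_point, any)
    zero_cells <- which(!ever_seen_cell)
    bs <- pd[use, paste0(dat$ab_labels, "[", sp, "]"), drop = FALSE]
    as_ <- pd[use, paste0(dat$det_labels, "[", sp, "]"), drop = FALSE]
    psi <- pd[use, paste0("psi[", sp, "]")]
    gm <- pd[use, paste0("gamma[", dat$sites, "]"), drop = FALSE]
    for (d in seq_along(use)) {
      lam <- exp(drop(dat$Xab %*% bs[d, ]) + gm[d, dat$site0 + 1L])
      phim <- matrix(plogis(drop(dat$Xdet %*% as_[d, ])), dat$n, dat$V)
      q <- exp(rowSums(log1p(-phim)))
      zp <- as.logical(seen_point)
      if (length(zero_cells)) {
        lc <- lam[zero_cells]; qc <- q[zero_cells]
        num <- psi[d] * (exp(-lc * (1 - qc)) - exp(-lc))
        den <- (1 - psi[d]) + psi[d] * exp(-lc * (1 - qc))
        pos <- rbinom(length(zero_cells), 1L, pmin(pmax(num / den, 0), 1))
        for (idx in which(pos == 1L))
          zp[cell_point[zero_cells[idx]]] <- TRUE
      }
      z[d, s, ] <- as.integer(zp)
    }
  }
  class(z) <- "cnm_zmatrix"
  z
}

#' Jaccard co-occurrence index of two binary occupancy vectors
#'
#' `J = sum(z_i z_j) / (sum(z_i) + sum(z_j) - sum(z_i z_j))`, the ratio of
#' jointly occupied points to points occupied by either species; 0 means
#' no co-occurrence, 1 perfect co-occurrence.
#'
#' @param z_i,z_j Binary vectors of equal length.
#' @return Jaccard index in \[0, 1\]; `NA` when both vectors are all zero
#'   (undefined, excluded from posterior summaries).
#' @export
jaccard <- function(z_i, z_j) {
  if (length(z_i) != length(z_j))
    stop("z vectors must have equal length")
  inter <- sum(z_i & z_j)
  union <- sum(z_i) + sum(z_j) - inter
  if (union == 0) return(NA_real_)
  inter / union
}

#' Posterior Jaccard indices for all species pairs
#'
#' Computes the Jaccard index per posterior draw for every pair of
#' species from a [build_z_matrix()] result, propagating the abundance
#' model's uncertainty into the co-occurrence estimates; 12 species give
#' 66 pairs.  Draws where a pair is undefined (both species absent from
#' every point) are dropped from that pair's summary and counted.
#'
#' @param zmat A `cnm_zmatrix`.
#' @return Data frame of class `cnm_jaccard`: `species_i`, `species_j`,
#'   posterior `mean`, `lower`, `upper`, and `n_dropped`.
#' @export
jaccard_posterior <- function(zmat) {
  dims <- dim(zmat)
  D <- dims[1]; S <- dims[2]
  species <- dimnames(zmat)[[2]]
  pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  jd <- matrix(NA_real_, D, nrow(pairs))
  for (d in seq_len(D)) {
    Z <- matrix(zmat[d, , ], nrow = S)
    inter <- tcrossprod(Z)
    occ <- rowSums(Z)
    un <- outer(occ, occ, "+") - inter
    J <- ifelse(un > 0, inter / un, NA_real_)
    jd[d, ] <- J[pairs]
  }
  out <- data.frame(species_i = species[pairs[, 1]],
                    species_j = species[pairs[, 2]],
                    t(apply(jd, 2, summ_ci)),
                    n_dropped = colSums(is.na(jd)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cnm_jaccard", class(out))
  out
}

#' Suite- and community-level coefficient summaries
#'
#' For every regression coefficient, the suite-level value in each
#' posterior draw is the mean of the member species' coefficients in that
#' draw; the community-level value is the corresponding hyper-mean draw.
#' Each row carries the 95% CrI significance flag.
#'
#' @param fit A `comm_nmix` fit with a suite map.
#' @param labels Coefficient labels to summarize (default: all abundance
#'   and detection coefficients).
#' @return Data frame: `parameter`, `level`, `name`, `mean`, `lower`,
#'   `upper`, `significant`.
#' @export
suite_summary <- function(fit, labels = c(fit$data$ab_labels,
                                          fit$data$det_labels)) {
  suites <- check_suites(fit)
  species <- fit$data$species
  rows <- list()
  for (lab in labels) {
    mu <- pooled_draws(fit, paste0("mu_", lab))[, 1]
    ci <- summ_ci(mu)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = lab, level = "community", name = "community", t(ci),
      significant = ci[["lower"]] > 0 | ci[["upper"]] < 0,
      stringsAsFactors = FALSE)
    sm <- pooled_draws(fit, paste0(lab, "[", species, "]"))
    for (su in unique(suites)) {
      member <- which(suites == su)
      if (length(member) == 0) stop("empty suite: ", su)
      dsu <- rowMeans(sm[, member, drop = FALSE])
      ci <- summ_ci(dsu)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = lab, level = "suite", name = su, t(ci),
        significant = ci[["lower"]] > 0 | ci[["upper"]] < 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translate a standardized coefficient into a natural-scale abundance change
#'
#' For a raw-scale covariate change `delta_raw`, each posterior draw
#' yields `delta_abundance = lambda_baseline * (exp(beta * delta_raw /
#' covariate_sd) - 1)`, i.e. the expected change in birds per plot from
#' the baseline expected abundance.
#'
#' @param beta_draws Posterior draws of the standardized coefficient.
#' @param covariate_sd Raw-scale standard deviation used in
#'   standardization (> 0).
#' @param delta_raw Raw-scale covariate change (e.g. -26 m2/ha of basal
#'   area).
#' @param baseline_lambda_draws Baseline expected abundance draws
#'   (recycled against `beta_draws`).
#' @return List with `draws` and posterior `mean`, `lower`, `upper`.
#' @export
rescale_effect <- function(beta_draws, covariate_sd, delta_raw,
                           baseline_lambda_draws = 1) {
  if (covariate_sd <= 0) stop("covariate_sd must be positive")
  base <- rep_len(baseline_lambda_draws, length(beta_draws))
  d <- base * (exp(beta_draws * delta_raw / covariate_sd) - 1)
  c(list(draws = d), as.list(summ_ci(d)))
}
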