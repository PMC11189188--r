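# pooled (chains stacked) draw matrix for selected parameters
pooled_draws <- function(x, pars = NULL) {
  a <- if (inherits(x, "comm_nmix")) x$draws else as_draws_array(x)
  if (is.null(pars)) pars <- dimnames(a)[[2]]
  miss <- setdiff(pars, dimnames(a)[[2]])
  if (length(miss))
    stop("unknown parameters: ", paste(miss, collapse = ", "))
  out <- do.call(rbind, lapply(seq_len(dim(a)[3]), function(ch)
    matrix(a[, pars, ch], ncol = length(pars))))
  colnames(out) <- pars
  out
}

hyper_par_names <- function(fit) {
  c(paste0("mu_", fit$data$ab_labels), paste0("sigma_", fit$data$ab_labels),
    paste0("mu_", fit$data$det_labels), paste0("sigma_", fit$data$det_labels),
    "sigma_site")
}

monitored <- function(fit) {
  if (!is.null(fit$config$monitor)) fit$config$monitor else hyper_par_names(fit)
}

#' @export
print.comm_nmix <- function(x, ...) {
  cat("Hierarchical community N-mixture model (zero-inflated)\n")
  cat(sprintf("  %d species, %d point-year cells, %d visits; %d site(s)\n",
              x$data$S, x$data$n, x$data$V, length(x$data$sites)))
  cat(sprintf("  %d chain(s) x %d kept draws (%.1f s)\n",
              dim(x$draws)[3], dim(x$draws)[1], x$runtime))
  s <- posterior_summary(x$draws, pars = monitored(x))
  cat("\nCommunity hyperparameters:\n")
  print(format_summary(s), row.names = FALSE)
  invisible(x)
}

format_summary <- function(s) {
  data.frame(parameter = s$parameter,
             mean = sprintf("%8.3f", s$mean),
             `95% CrI` = sprintf("(%.3f, %.3f)", s$lower, s$upper),
             rhat = ifelse(is.na(s$rhat), "  -", sprintf("%.3f", s$rhat)),
             sig = ifelse(s$significant, "*", ""),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Summarize a fitted community N-mixture model
#'
#' @param object A `comm_nmix` fit.
#' @param pars Parameters to summarize (default: the monitored set, i.e.
#'   all community hyperparameters unless the config says otherwise).
#' @param ... Passed to [posterior_summary()].
#' @return A `cnm_summary` data frame.
#' @export
summary.comm_nmix <- function(object, pars = monitored(object), ...) {
  posterior_summary(object$draws, pars = pars, ...)
}

#' @export
print.cnm_summary <- function(x, ...) {
  print(format_summary(x), row.names = FALSE)
  invisible(x)
}

#' Posterior-mean species coefficients
#'
#' @param object A `comm_nmix` fit.
#' @param which `"abundance"` or `"detection"`.
#' @param ... Unused.
#' @return Species x coefficient matrix of posterior means.
#' @export
coef.comm_nmix <- function(object, which = c("abundance", "detection"), ...) {
  which <- match.arg(which)
  labs <- if (which == "abundance") object$data$ab_labels else
    object$data$det_labels
  out <- sapply(labs, function(l) {
    colMeans(pooled_draws(object, paste0(l, "[", object$data$species, "]")))
  })
  rownames(out) <- object$data$species
  colnames(out) <- labs
  out
}

#' Trace plots of monitored parameters
#'
#' @param x A `comm_nmix` fit.
#' @param pars Parameters to plot (default: first 12 monitored).
#' @param ... Unused.
#' @export
plot.comm_nmix <- function(x, pars = head(monitored(x), 12), ...) {
  a <- x$draws
  old <- par(mfrow = c(ceiling(length(pars) / 3), min(3, length(pars))),
             mar = c(2, 2, 2, 0.5))
  on.exit(par(old))
  for (pp in pars) {
    matplot(a[, pp, ], type = "l", lty = 1, main = pp, xlab = "", ylab = "")
  }
  invisible(x)
}

# posterior-mean expected per-visit count E[y] = psi * lambda * phi per
# species x cell x visit, on the observation scale
#' @export
fitted.comm_nmix <- function(object, ...) {
  dat <- object$data
  out <- vector("list", dat$S)
  for (s in seq_len(dat$S)) {
    sp <- dat$species[s]
    bs <- colMeans(pooled_draws(object,
                                paste0(dat$ab_labels, "[", sp, "]")))
    as_ <- colMeans(pooled_draws(object,
                                 paste0(dat$det_labels, "[", sp, "]")))
    psi <- mean(pooled_draws(object, paste0("psi[", sp, "]")))
    g <- colMeans(pooled_draws(object, paste0("gamma[", dat$sites, "]")))
    lam <- exp(drop(dat$Xab %*% bs) + g[dat$site0 + 1L])
    phi <- plogis(drop(dat$Xdet %*% as_))
    out[[s]] <- psi * rep(lam, dat$V) * phi
  }
  names(out) <- dat$species
  out
}

#' @export
residuals.comm_nmix <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  fv <- fitted(object)
  dat <- object$data
  out <- vector("list", dat$S)
  for (s in seq_len(dat$S)) {
    y <- as.vector(t(dat$Yt[[s]]))      # cell-major within visit blocks
    r <- y - fv[[s]]
    if (type == "pearson") r <- r / sqrt(pmax(fv[[s]], 1e-12))
    out[[s]] <- r
  }
  names(out) <- dat$species
  out
}

#' Posterior-predictive count simulation from a fitted model
#'
#' Draws whole replicate count tables: for each requested simulation a
#' posterior draw is selected, latent states `a` and `M` are drawn from
#' the process model at those parameters, and per-visit counts from the
#' detection model.
#'
#' @param object A `comm_nmix` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of count data frames shaped like the fitting data.
#' @export
simulate.comm_nmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- object$data
  a <- object$draws
  total <- dim(a)[1] * dim(a)[3]
  picks <- sample.int(total, nsim, replace = nsim > total)
  pd <- pooled_draws(object)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    row <- pd[picks[i], ]
    reps <- vector("list", dat$S)
    for (s in seq_len(dat$S)) {
      sp <- dat$species[s]
      bs <- row[paste0(dat$ab_labels, "[", sp, "]")]
      as_ <- row[paste0(dat$det_labels, "[", sp, "]")]
      psi <- row[paste0("psi[", sp, "]")]
      g <- row[paste0("gamma[", dat$sites, "]")]
      lam <- exp(drop(dat$Xab %*% bs) + g[dat$site0 + 1L])
      M <- rpois(dat$n, rbinom(dat$n, 1L, psi) * lam)
      phi <- plogis(drop(dat$Xdet %*% as_))
      y <- rbinom(dat$n * dat$V, rep(M, dat$V), phi)
      reps[[s]] <- data.frame(
        species = sp, site = rep(dat$cells$site, dat$V),
        point = rep(dat$cells$point, dat$V),
        year = rep(dat$cells$year, dat$V),
        visit = rep(seq_len(dat$V), each = dat$n), count = y,
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, reps)
  }
  out
}
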