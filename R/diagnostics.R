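#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance ratio: with m chains of n draws,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the PSRF is `sqrt(((n-1)/n W + B/n) / W)`.  Values below 1.1
#' are conventionally taken as convergence.
#'
#' @param draws A `cnm_draws` array (iterations x parameters x chains), or
#'   a matrix/list coercible to one.
#' @param min_draws Minimum draws per chain.
#' @return Named numeric vector of R-hat values, with attribute
#'   `degenerate`: logical flag per parameter, `TRUE` where every chain
#'   has zero within-chain variance (R-hat is `NA` there rather than a
#'   crash).
#' @export
gelman_rubin <- function(draws, min_draws = 10) {
  x <- as_draws_array(draws)
  m <- dim(x)[3]; n <- dim(x)[1]
  if (m < 2) stop("convergence assessment needs at least 2 chains")
  if (n < min_draws) stop("need at least ", min_draws, " draws per chain")
  np <- dim(x)[2]
  rhat <- numeric(np)
  degen <- logical(np)
  for (j in seq_len(np)) {
    ch <- x[, j, , drop = TRUE]
    W <- mean(apply(ch, 2, var))
    B_over_n <- var(colMeans(ch))
    if (!is.finite(W) || W <= 0) {
      rhat[j] <- NA_real_
      degen[j] <- TRUE
      next
    }
    vplus <- (n - 1) / n * W + B_over_n
    rhat[j] <- sqrt(vplus / W)
  }
  names(rhat) <- dimnames(x)[[2]]
  attr(rhat, "degenerate") <- setNames(degen, names(rhat))
  rhat
}

as_draws_array <- function(draws) {
  if (is.array(draws) && length(dim(draws)) == 3) return(draws)
  if (is.list(draws) && !is.array(draws)) {
    draws <- lapply(draws, as.matrix)
    return(array(unlist(draws),
                 dim = c(nrow(draws[[1]]), ncol(draws[[1]]), length(draws)),
                 dimnames = list(NULL, colnames(draws[[1]]), NULL)))
  }
  stop("draws must be an iterations x parameters x chains array or a list of chain matrices")
}

#' Posterior summary table with the credible-interval significance rule
#'
#' Pools chains and reports, per parameter, the posterior mean, the
#' equal-tailed 95% interval (empirical quantiles, default type), the
#' Gelman-Rubin R-hat, and a significance flag that is `TRUE` exactly
#' when the 95% credible interval excludes 0.
#'
#' @param draws A `cnm_draws` array.
#' @param pars Optional parameter names (default all).
#' @param prob Interval mass (default 0.95).
#' @return Data frame of class `cnm_summary` with columns `parameter`,
#'   `mean`, `lower`, `upper`, `rhat`, `significant`.
#' @export
posterior_summary <- function(draws, pars = NULL, prob = 0.95) {
  x <- as_draws_array(draws)
  if (!is.null(pars)) {
    miss <- setdiff(pars, dimnames(x)[[2]])
    if (length(miss))
      stop("unknown parameters: ", paste(miss, collapse = ", "))
    x <- x[, pars, , drop = FALSE]
  }
  a <- (1 - prob) / 2
  rhat <- if (dim(x)[3] >= 2) gelman_rubin(x) else rep(NA_real_, dim(x)[2])
  pooled <- apply(x, 2, identity)   # iterations*chains x parameters
  if (is.null(dim(pooled))) pooled <- matrix(pooled, ncol = dim(x)[2])
  mn <- colMeans(pooled)
  qs <- apply(pooled, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(parameter = dimnames(x)[[2]], mean = mn,
                    lower = qs[1, ], upper = qs[2, ],
                    rhat = as.numeric(rhat),
                    significant = qs[1, ] > 0 | qs[2, ] < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cnm_summary", class(out))
  out
}
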