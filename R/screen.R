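#' Greedy collinearity screen on Pearson correlations
#'
#' Walks the candidate covariates in priority order, retaining each one
#' unless its absolute Pearson correlation with an already-retained
#' covariate exceeds the threshold; models are then fit on the retained
#' set only.  The default priority mirrors forest-management practice:
#' basal area first (the standard stand-density measure), then grass,
#' woody, VOR2, then everything else in table order.
#'
#' @param table Data frame of candidate covariates (numeric columns), or a
#'   `cnm_covariates` object (its point-level covariates are used).
#' @param threshold Exclusion threshold on \|r\|, in (0, 1].
#' @param priority Character vector giving the retention order; covariates
#'   not listed are appended in column order.
#' @return An object of class `cnm_screen`: list with the full `cor`
#'   matrix, `retained` covariates, and an `excluded` data frame naming,
#'   for every exclusion, the retained partner and the offending r.
#' @export
correlation_screen <- function(table, threshold = 0.7,
                               priority = c("basal", "grass", "woody", "vor2")) {
  if (inherits(table, "cnm_covariates")) {
    num <- vapply(table$points, is.numeric, logical(1))
    table <- table$points[, setdiff(names(table$points)[num],
                                    c("point", "site", "year"))]
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (nrow(table) < 3)
    stop("need at least 3 records to screen correlations")
  vars <- names(table)
  ord <- c(intersect(priority, vars), setdiff(vars, priority))
  cm <- cor(as.matrix(table[, ord, drop = FALSE]))

  retained <- character(0)
  excluded <- data.frame(covariate = character(0), partner = character(0),
                         r = numeric(0), stringsAsFactors = FALSE)
  for (v in ord) {
    if (length(retained)) {
      rs <- cm[v, retained]
      hit <- which(abs(rs) > threshold)
      if (length(hit)) {
        j <- hit[which.max(abs(rs[hit]))]
        excluded <- rbind(excluded, data.frame(
          covariate = v, partner = retained[j], r = unname(rs[j]),
          stringsAsFactors = FALSE))
        next
      }
    }
    retained <- c(retained, v)
  }
  structure(list(cor = cm, retained = retained, excluded = excluded,
                 threshold = threshold),
            class = "cnm_screen")
}

#' @export
print.cnm_screen <- function(x, ...) {
  cat("Collinearity screen (|r| > ", x$threshold, ")\n", sep = "")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  excluded %s (|r| = %.2f with %s)\n",
                  x$excluded$covariate[i], abs(x$excluded$r[i]),
                  x$excluded$partner[i]))
  } else cat("  nothing excluded\n")
  invisible(x)
}

#' Compare a covariate between treatment and control groups
#'
#' Welch two-sample t-test of `values` split by the binary `group` labels,
#' reporting the statistic with its honest degrees of freedom, the
#' p-value, and group means (direction of difference).
#'
#' @param values Numeric vector.
#' @param group Vector of two group labels, same length as `values`.  The
#'   statistic is computed as first group minus second (by factor order).
#' @return List of class `cnm_ttest`: `t`, `df`, `p`, `means` (named),
#'   `difference`.
#' @export
compare_groups <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels")
  sizes <- table(group)
  if (any(sizes < 2))
    stop("both groups need at least 2 members")
  tt <- t.test(values ~ group)
  means <- setNames(as.numeric(tt$estimate), levels(group))
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, means = means,
                 difference = unname(diff(rev(means)))),
            class = "cnm_ttest")
}

#' @export
print.cnm_ttest <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.1f, p = %.3g\n", x$t, x$df, x$p))
  cat(sprintf("  means: %s = %.3f, %s = %.3f\n",
              names(x$means)[1], x$means[1], names(x$means)[2], x$means[2]))
  invisible(x)
}

#' Treatment-vs-control comparison for every vegetation covariate
#'
#' @param covariates A `cnm_covariates` object.
#' @param vars Covariates to compare (default: all numeric vegetation
#'   columns).
#' @return Data frame with one row per covariate: t, df, p, group means.
#' @export
compare_treatment_groups <- function(covariates,
                                     vars = intersect(
                                       c("grass", "woody", "vor2", "basal"),
                                       names(covariates$points))) {
  pts <- covariates$points
  rows <- lapply(vars, function(v) {
    ct <- compare_groups(pts[[v]], pts$treatment)
    data.frame(covariate = v, t = ct$t, df = ct$df, p = ct$p,
               mean_control = ct$means[["control"]],
               mean_treatment = ct$means[["treatment"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
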