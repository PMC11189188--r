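count_cols <- c("species", "site", "point", "year", "visit", "count")
point_cols <- c("point", "site", "year", "treatment")
visit_cols <- c("point", "year", "visit", "date", "wind", "disturbance")

read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             comment.char = "#")
}

write_tsv <- function(x, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and validate a long-format count table
#'
#' Expects a delimited file (tab-separated) with columns `species`,
#' `site`, `point`, `year`, `visit`, `count`.  Counts must be
#' non-negative integers and each species x point x year x visit must
#' appear at most once; violations are reported with row numbers.
#'
#' @param path File path.
#' @return A `cnm_counts` data frame.
#' @export
read_counts <- function(path) {
  x <- read_tsv(path)
  miss <- setdiff(count_cols, names(x))
  if (length(miss))
    stop("count table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(x$count < 0 | x$count != floor(x$count) | is.na(x$count))
  if (length(bad))
    stop("invalid counts (negative, missing or non-integer) at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  key <- paste(x$species, x$point, x$year, x$visit)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated survey rows at row(s): ",
         paste(head(dup, 10), collapse = ", "))
  x <- x[, count_cols]
  class(x) <- c("cnm_counts", class(x))
  x
}

#' Write a count table
#'
#' @param counts A count data frame.
#' @param path File path.
#' @param config_hash Optional provenance hash written as a header comment.
#' @export
write_counts <- function(counts, path, config_hash = NULL) {
  write_tsv(as.data.frame(counts)[, count_cols], path, config_hash)
  invisible(path)
}

#' Read and validate covariate tables
#'
#' Point-level table: `point`, `site`, `year`, `treatment` plus vegetation
#' covariates (percent covariates must lie in \[0, 100\], basal area must
#' be non-negative).  Visit-level table: `point`, `year`, `visit`,
#' `date`, `wind`, `disturbance`.
#'
#' @param points_path,visits_path File paths.
#' @return A `cnm_covariates` object (raw scale).
#' @export
read_covariates <- function(points_path, visits_path) {
  pts <- read_tsv(points_path)
  need <- c(point_cols, c("grass", "woody", "vor2", "basal"))
  miss <- setdiff(need, names(pts))
  if (length(miss))
    stop("point covariate table is missing columns: ",
         paste(miss, collapse = ", "), " (required: ",
         paste(need, collapse = ", "), ")")
  for (pc in c("grass", "woody", "vor2")) {
    bad <- which(pts[[pc]] < 0 | pts[[pc]] > 100)
    if (length(bad))
      stop("'", pc, "' outside [0, 100] at row(s): ",
           paste(head(bad, 10), collapse = ", "))
  }
  bad <- which(pts$basal < 0)
  if (length(bad))
    stop("'basal' negative at row(s): ", paste(head(bad, 10), collapse = ", "))
  if (!all(pts$treatment %in% c("treatment", "control")))
    stop("'treatment' must be 'treatment' or 'control'")

  vis <- read_tsv(visits_path)
  miss <- setdiff(visit_cols, names(vis))
  if (length(miss))
    stop("visit covariate table is missing columns: ",
         paste(miss, collapse = ", "))
  out <- list(points = pts, visits = vis[, visit_cols],
              standardized = FALSE)
  class(out) <- "cnm_covariates"
  out
}

#' Write covariate tables
#'
#' @param covariates A `cnm_covariates` object.
#' @param points_path,visits_path File paths.
#' @param config_hash Optional provenance hash.
#' @export
write_covariates <- function(covariates, points_path, visits_path,
                             config_hash = NULL) {
  write_tsv(covariates$points, points_path, config_hash)
  write_tsv(covariates$visits, visits_path, config_hash)
  invisible(c(points_path, visits_path))
}

#' Write posterior draws as a long table
#'
#' One row per chain x iteration x parameter.
#'
#' @param draws A `cnm_draws` array.
#' @param path File path.
#' @param config_hash Optional provenance hash.
#' @export
write_draws <- function(draws, path, config_hash = NULL) {
  a <- as_draws_array(draws)
  d <- dim(a)
  long <- data.frame(
    chain = rep(seq_len(d[3]), each = d[1] * d[2]),
    iteration = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    parameter = rep(rep(dimnames(a)[[2]], each = d[1]), times = d[3]),
    value = as.vector(a), stringsAsFactors = FALSE)
  write_tsv(long, path, config_hash)
  invisible(path)
}
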