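#' k-nearest-neighbour imputation for below-LLOQ entries
#'
#' For each censored row, finds the `k` nearest uncensored (donor) rows by
#' Euclidean distance on standardised covariates, averages the donors'
#' values of the censored variable, and truncates the average at the LLOQ
#' (`min(mean, lloq)`) so imputed values never exceed the detection limit.
#' Covariates are standardised to z-scores using mean and standard deviation
#' over the full table; distance ties are broken by row order.
#'
#' @param data Data frame containing `bloq_var`, its censoring flag column
#'   and the distance covariates.
#' @param bloq_var Name of the left-censored column. Its logical companion
#'   column `"<bloq_var>_censored"` marks the rows to impute.
#' @param covariates Character vector of covariate columns used for the
#'   distance. Constant columns are dropped from the distance.
#' @param lloq Positive threshold.
#' @param k Number of donors to average (default 5). If fewer donors exist,
#'   all are used and a warning is issued.
#'
#' @return Numeric vector of completed `bloq_var` values (uncensored entries
#'   unchanged).
#' @export
impute_knn <- function(data, bloq_var, covariates, lloq, k = 5L) {
  flag <- data[[paste0(bloq_var, "_censored")]]
  if (is.null(flag)) stop("missing censoring flag column for ", bloq_var)
  flag <- as.logical(flag)
  x <- data[[bloq_var]]
  covm <- as.matrix(data[covariates])
  if (any(!is.finite(covm))) stop("distance covariates must be finite")

  donors <- which(!flag)
  if (length(donors) == 0L) stop("no donors: every row is censored")
  if (length(donors) < k) {
    warning(sprintf("only %d donors available; using all of them (k = %d)",
                    length(donors), k))
    k <- length(donors)
  }

  std <- standardize_columns(covm)
  imputed <- .knn_mean_cpp(std$z[flag, , drop = FALSE],
                           std$z[donors, , drop = FALSE],
                           x[donors], as.integer(k))
  x[flag] <- pmin(imputed, lloq)
  x
}

# z-scores from full-table mean/sd; constant columns dropped.
standardize_columns <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  keep <- which(sd > 0)
  if (length(keep) == 0L) stop("all distance covariates are constant")
  z <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep]), 2L, sd[keep], "/")
  list(z = z, mean = mu[keep], sd = sd[keep], keep = keep)
}

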