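#' Left-censored vectors
#'
#' A `censored_vector` stores a numeric variable subject to a lower limit of
#' quantification (LLOQ): the observed values, a per-element censoring flag,
#' and the threshold itself. Elements at or below the LLOQ are flagged as
#' censored and their `values` slot holds the sentinel `lloq` (never `NA`),
#' so downstream completion rules always read a defined number; every
#' consumer must branch on the `censored` flag, not on the stored value.
#'
#' @param values Numeric vector. Uncensored entries are the measured values;
#'   censored entries must equal `lloq` (the sentinel convention).
#' @param censored Logical vector of the same length.
#' @param lloq Positive scalar: the lower limit of quantification.
#'
#' @return An object of class `censored_vector` with fields `values`,
#'   `censored` and `lloq`.
#' @seealso [apply_lloq()] to censor a clean vector,
#'   [lloq_for_proportion()] to pick a threshold.
#' @export
censored_vector <- function(values, censored, lloq) {
  stopifnot(is.numeric(values), is.logical(censored))
  if (length(values) != length(censored)) {
    stop("`values` and `censored` must have the same length")
  }
  if (!is.numeric(lloq) || length(lloq) != 1L || !is.finite(lloq) || lloq <= 0) {
    stop("`lloq` must be a single positive number")
  }
  if (anyNA(censored)) stop("`censored` must not contain NA")
  if (any(!is.finite(values))) stop("`values` must be finite")
  if (any(!censored & values <= lloq)) {
    stop("uncensored values must exceed the LLOQ")
  }
  values[censored] <- lloq  # enforce the sentinel
  structure(list(values = values, censored = censored, lloq = lloq),
            class = "censored_vector")
}

#' @export
print.censored_vector <- function(x, ...) {
  cat(sprintf("<censored_vector> n = %d, LLOQ = %g, censored = %d (%.1f%%)\n",
              length(x$values), x$lloq, sum(x$censored),
              100 * mean(x$censored)))
  invisible(x)
}

#' @export
length.censored_vector <- function(x) length(x$values)

#' Censor a numeric vector at a lower limit of quantification
#'
#' Applies the left-censoring observation rule: every element at or below
#' `lloq` is flagged censored and its value replaced by the sentinel `lloq`;
#' elements strictly above the threshold pass through unchanged. Ties
#' (`x == lloq`) are censored.
#'
#' @param x Finite numeric vector of clean (fully observed) values.
#' @param lloq Positive scalar threshold.
#'
#' @return A [censored_vector()]. The attribute `"prop_censored"` records the
#'   observed censored fraction.
#' @examples
#' cv <- apply_lloq(c(0.1, 0.7, 0.59), lloq = 0.6)
#' cv$censored  # TRUE FALSE TRUE
#' @export
apply_lloq <- function(x, lloq) {
  stopifnot(is.numeric(x))
  if (length(x) && any(!is.finite(x))) stop("`x` must be finite")
  censored <- x <= lloq
  cv <- censored_vector(replace(x, censored, lloq), censored, lloq)
  attr(cv, "prop_censored") <- if (length(x)) mean(censored) else NA_real_
  cv
}

#' Uncensored values of a censored vector
#'
#' @param cv A [censored_vector()].
#' @return Numeric vector of the values strictly above the LLOQ.
#' @export
uncensored_values <- function(cv) {
  stopifnot(inherits(cv, "censored_vector"))
  cv$values[!cv$censored]
}

#' Threshold giving a target below-LLOQ proportion
#'
#' Returns the `p`-quantile of a generating distribution, i.e. the LLOQ at
#' which censoring fresh draws from that distribution yields an expected
#' below-LLOQ proportion of `p`. Closed-form quantiles are used for the beta
#' and normal families; distributions without a quantile rule (e.g. the
#' Bernoulli, or an arbitrary outcome mixture) are rejected — for the
#' simulated outcome's mixture distribution see [outcome_lloq()], which
#' estimates the quantile by Monte Carlo.
#'
#' @param dist A [dist_beta()] or [dist_normal()] specification.
#' @param p Target proportion in (0, 1).
#'
#' @return A single numeric threshold.
#' @examples
#' lloq_for_proportion(dist_beta(5, 5), 0.5)   # 0.5 (symmetric beta median)
#' lloq_for_proportion(dist_beta(2, 8), 0.2)
#' @export
lloq_for_proportion <- function(dist, p) {
  stopifnot(inherits(dist, "bloq_dist"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("invalid proportion: `p` must lie strictly in (0, 1)")
  }
  dist_quantile(dist, p)
}
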