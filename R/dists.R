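#' Distribution specifications for covariate generation
#'
#' Lightweight specification objects for the parametric families used by the
#' simulation engine: beta, normal (parameterised by mean and standard
#' deviation) and Bernoulli. They carry just enough structure to draw random
#' variates, evaluate quantiles and transform latent standard-normal draws
#' (the Gaussian-copula margin transform).
#'
#' @param shape1,shape2 Positive beta shape parameters.
#' @param mean Mean of the normal distribution.
#' @param sd Positive standard deviation of the normal distribution.
#' @param prob Success probability in (0, 1).
#'
#' @return An object of class `bloq_dist`.
#' @examples
#' dist_beta(8, 2)
#' dist_normal(53, 4.17)
#' dist_bernoulli(0.6)
#' @name bloq_dist
NULL

#' @rdname bloq_dist
#' @export
dist_beta <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), is.numeric(shape2), shape1 > 0, shape2 > 0)
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2),
            class = "bloq_dist")
}

#' @rdname bloq_dist
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd),
            class = "bloq_dist")
}

#' @rdname bloq_dist
#' @export
dist_bernoulli <- function(prob) {
  stopifnot(is.numeric(prob), prob > 0, prob < 1)
  structure(list(family = "bernoulli", prob = prob), class = "bloq_dist")
}

#' @export
print.bloq_dist <- function(x, ...) {
  cat("<bloq_dist>", dist_label(x), "\n")
  invisible(x)
}

dist_label <- function(dist) {
  switch(dist$family,
    beta      = sprintf("Beta(%g, %g)", dist$shape1, dist$shape2),
    normal    = sprintf("Normal(mean = %g, sd = %g)", dist$mean, dist$sd),
    bernoulli = sprintf("Bernoulli(%g)", dist$prob),
    dist$family
  )
}

dist_draw <- function(dist, n) {
  switch(dist$family,
    beta      = stats::rbeta(n, dist$shape1, dist$shape2),
    normal    = stats::rnorm(n, dist$mean, dist$sd),
    bernoulli = stats::rbinom(n, 1L, dist$prob),
    stop("unsupported family: ", dist$family)
  )
}

dist_quantile <- function(dist, p) {
  switch(dist$family,
    beta   = stats::qbeta(p, dist$shape1, dist$shape2),
    normal = stats::qnorm(p, dist$mean, dist$sd),
    stop("no quantile rule for family '", dist$family, "'")
  )
}

# Margin transform of a standard-normal latent draw; exact for each family so
# copula coupling leaves the marginal distribution untouched.
dist_from_latent <- function(dist, z) {
  switch(dist$family,
    normal    = dist$mean + dist$sd * z,
    beta      = stats::qbeta(stats::pnorm(z), dist$shape1, dist$shape2),
    bernoulli = as.numeric(z > stats::qnorm(1 - dist$prob)),
    stop("unsupported family: ", dist$family)
  )
}
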