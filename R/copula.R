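#' Correlated draws from two arbitrary margins (Gaussian copula)
#'
#' Generates a pair of vectors whose marginal distributions exactly follow
#' `dist_a` and `dist_b` while their Pearson correlation on the observed
#' scale matches `rho_target`. A latent bivariate standard normal with
#' correlation `rho_z` is drawn and each coordinate is pushed through its
#' margin's transform (linear for normal margins, probability-integral
#' transform for beta, thresholding for Bernoulli). Because those
#' transforms distort correlation, `rho_z` is calibrated by monotone
#' bisection on a seeded pilot sample of 10^6 latent draws with common
#' random numbers, until the pilot Pearson correlation is within 0.002 of
#' the target; the calibration is cached per (margin pair, target) for the
#' session.
#'
#' @param dist_a,dist_b Margin specifications ([dist_beta()],
#'   [dist_normal()] or [dist_bernoulli()]).
#' @param rho_target Target Pearson correlation, `|rho_target| < 1`. Targets
#'   beyond what the margin pair can support (the Frechet-type bound of the
#'   copula family) are rejected.
#' @param n Number of draws.
#'
#' @return A list with numeric vectors `a` and `b` of length `n` and the
#'   attribute `"latent_rho"`.
#' @export
draw_correlated_pair <- function(dist_a, dist_b, rho_target, n) {
  stopifnot(inherits(dist_a, "bloq_dist"), inherits(dist_b, "bloq_dist"))
  if (abs(rho_target) >= 1) stop("|rho_target| must be < 1")
  rho_z <- if (rho_target == 0) 0 else {
    calibrate_latent_rho(dist_a, dist_b, rho_target)
  }
  z1 <- stats::rnorm(n)
  z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n)
  structure(list(a = dist_from_latent(dist_a, z1),
                 b = dist_from_latent(dist_b, z2)),
            latent_rho = rho_z)
}

.bloqreg_cache <- new.env(parent = emptyenv())

dist_key <- function(dist) {
  paste(unlist(dist), collapse = ",")
}

# Latent correlation such that the observed-scale Pearson correlation of the
# transformed margins hits rho_target. Common random numbers make the pilot
# correlation a monotone increasing function of rho_z, so plain bisection
# applies.
calibrate_latent_rho <- function(dist_a, dist_b, rho_target,
                                 pilot_n = 1e6, tol = 0.002) {
  key <- paste("rho", dist_key(dist_a), dist_key(dist_b), rho_target,
               sep = "|")
  cached <- .bloqreg_cache[[key]]
  if (!is.null(cached)) return(cached)

  pilot <- with_local_seed(190443201L, {
    list(z1 = stats::rnorm(pilot_n), z2 = stats::rnorm(pilot_n))
  })
  corr_at <- function(rho_z) {
    zb <- rho_z * pilot$z1 + sqrt(1 - rho_z^2) * pilot$z2
    stats::cor(dist_from_latent(dist_a, pilot$z1),
               dist_from_latent(dist_b, zb))
  }
  s <- sign(rho_target)
  lo <- 0
  hi <- s * 0.99999
  if (s * corr_at(hi) < s * rho_target - tol) {
    stop(sprintf(
      "infeasible correlation: target %.3f exceeds the maximum (~%.3f) attainable for these margins",
      rho_target, corr_at(hi)))
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    cm <- corr_at(mid)
    if (abs(cm - rho_target) < tol) {
      lo <- hi <- mid
      break
    }
    if (s * cm < s * rho_target) lo <- mid else hi <- mid
  }
  rho_z <- (lo + hi) / 2
  .bloqreg_cache[[key]] <- rho_z
  rho_z
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
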