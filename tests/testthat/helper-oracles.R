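# Independent oracle: dense-grid trapezoid evaluation of E(X | X < lloq)
# under the Gaussian KDE of the uncensored sample only. Kept deliberately
# separate from the package's own integration code paths.
oracle_conditional_mean <- function(obs, lloq, grid_n = 20000) {
  m <- length(obs)
  h <- 1.06 * sd(obs) * m^(-1 / 5)
  g <- seq(max(0, min(obs) - 3 * h), lloq, length.out = grid_n)
  f <- sapply(g, function(x) mean(dnorm((x - obs) / h)) / h)
  num <- sum((g[-1] * f[-1] + g[-grid_n] * f[-grid_n]) * diff(g)) / 2
  den <- sum((f[-1] + f[-grid_n]) * diff(g)) / 2
  num / den
}
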