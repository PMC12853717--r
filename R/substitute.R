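#' Fixed-value substitution for below-LLOQ entries
#'
#' Replaces every censored entry of a left-censored vector by a fixed
#' constant: 0, the LLOQ itself, LLOQ/2 (the mean of a uniform density on
#' (0, LLOQ)), or LLOQ/sqrt(2) — the point splitting the mass of a
#' triangular density on (0, LLOQ) in half, i.e. the solution of
#' `integral(l..L) c*x dx = 1/2 integral(0..L) c*x dx`. Uncensored entries
#' are carried through unchanged.
#'
#' @param cv A [censored_vector()].
#' @param rule One of `"zero"`, `"lloq"`, `"half"`, `"sqrt2"`.
#'
#' @return Numeric vector of completed values, same length as `cv`.
#' @examples
#' cv <- apply_lloq(c(0.1, 0.7, 0.59), 0.6)
#' substitute_bloq(cv, "half")   # censored slots become 0.3
#' substitute_bloq(cv, "sqrt2")  # censored slots become 0.6 / sqrt(2)
#' @export
substitute_bloq <- function(cv, rule = c("zero", "lloq", "half", "sqrt2")) {
  stopifnot(inherits(cv, "censored_vector"))
  rule <- match.arg(rule)
  replace(cv$values, cv$censored, substitution_value(cv$lloq, rule))
}

substitution_value <- function(lloq, rule) {
  switch(rule,
    zero  = 0,
    lloq  = lloq,
    half  = lloq / 2,
    sqrt2 = lloq / sqrt(2),
    stop("unknown substitution rule: ", rule)
  )
}

#' Two-compartment design for a left-censored covariate
#'
#' Splits a left-censored covariate into two regressors: a binary indicator
#' `x_bin` that is 1 where the observation lies at or below the LLOQ, and a
#' continuous part `x_cont` holding the observed value where uncensored and
#' a fixed fill value (any constant in `[0, lloq]`) where censored. Entering
#' both into the regression separates the influence of being below the
#' detection limit from the influence of the measured magnitude; when the
#' indicator is in the model, the coefficient on `x_cont` is invariant to
#' the choice of fill.
#'
#' @param cv A [censored_vector()].
#' @param fill Constant placed in censored slots of `x_cont`; must lie in
#'   `[0, lloq]`. Default 0.
#'
#' @return A list with numeric components `x_bin` (0/1) and `x_cont`.
#' @examples
#' cv <- apply_lloq(c(0.1, 0.7, 0.59), 0.6)
#' two_compartment_design(cv)  # x_bin = (1,0,1), x_cont = (0, 0.7, 0)
#' @export
two_compartment_design <- function(cv, fill = 0) {
  stopifnot(inherits(cv, "censored_vector"))
  if (!is.numeric(fill) || length(fill) != 1L || is.na(fill) ||
      fill < 0 || fill > cv$lloq) {
    stop("invalid fill: must be a single value in [0, lloq]")
  }
  list(
    x_bin  = as.numeric(cv$censored),
    x_cont = replace(cv$values, cv$censored, fill)
  )
}
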