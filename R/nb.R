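# Negative binomial core. The parameterization is pinned so that mixtures
# stay in the family: with a success probability p shared across
# components, NB(r1, p) + NB(r2, p) ~ NB(r1 + r2, p). Concretely,
#
#   pmf(k; r, p) = Gamma(k + r) / (Gamma(r) k!) * p^k * (1 - p)^r
#
# with mean r * p / (1 - p). This equals stats::dnbinom(k, size = r,
# prob = 1 - p); the log-pmf is written out in gamma-function form because
# the model's gradients need the same pieces and r is not restricted to
# integers.

#' Negative binomial log-probability mass
#'
#' Log of `Gamma(k + r) / (Gamma(r) k!) * p^k * (1 - p)^r`. Under this
#' convention the mean is `r * p / (1 - p)` and rates are additive across
#' components sharing `p`, which is what lets a spot's mixed expression
#' stay negative binomial.
#'
#' @param k Non-negative integer count(s).
#' @param r Positive rate parameter(s), recycled against `k`.
#' @param p Success probability in (0, 1), recycled.
#' @return Log-probability, same length as the recycled arguments.
#' @export
nb_log_pmf <- function(k, r, p) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k))) {
    abort("`k` must be non-negative integer-valued")
  }
  if (any(!is.finite(r)) || any(r <= 0)) abort("`r` must be positive")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly in (0, 1)")
  }
  lgamma(k + r) - lgamma(r) - lgamma(k + 1) + k * log(p) + r * log1p(-p)
}

# Numerically stable softplus and its derivative (the sigmoid). softplus
# maps unconstrained optimizer parameters to the positive rates; sigmoid
# maps logits to success probabilities.
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) plogis(x)

# Inverse softplus, for initializing unconstrained parameters at a target
# positive value: x = log(exp(y) - 1), stable for large y.
inv_softplus <- function(y) {
  ifelse(y > 30, y, log(expm1(y)))
}
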