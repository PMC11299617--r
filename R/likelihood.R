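# Poisson observation model: cost function and tempered log posterior.

#' Mean Poisson cost of a model on a curve
#'
#' The negative log-likelihood per data point, up to the data-only constant:
#' \deqn{E(\Xi) = \frac{1}{N}\sum_{i=1}^N \left[\lambda_i - y_i \log \lambda_i\right],
#'   \qquad \lambda_i = T\, I(q_i, \Xi),}
#' so that the likelihood satisfies
#' \eqn{p(D \mid \Xi) = C(D) \exp(-N E)} with
#' \eqn{C(D) = \prod_i 1/y_i!}. The constant is identical for every candidate
#' model on the same data and cancels from posterior model probabilities, so
#' it is dropped; `log_data_constant()` recovers it when absolute
#' log-evidence values are wanted.
#'
#' @param params Model parameters (`sphere_params` or `flat_params`).
#' @param curve A [sas_curve()].
#' @return Scalar mean cost E.
#' @export
poisson_cost <- function(params, curve) {
  stopifnot(inherits(curve, "sas_curve"))
  lambda <- curve$T * intensity(params, curve$q)
  if (any(lambda <= 0) || anyNA(lambda))
    stop("model mean must be strictly positive at every point (is B > 0?)")
  mean(lambda - curve$y * log(lambda))
}

#' @rdname poisson_cost
#' @export
log_data_constant <- function(curve) {
  stopifnot(inherits(curve, "sas_curve"))
  -sum(lgamma(curve$y + 1))
}

#' Tempered unnormalized log posterior
#'
#' \eqn{-\beta N E(\Xi) + \log \varphi(\Xi)}: at `beta = 0` this is the log
#' prior, at `beta = 1` the log posterior up to the data-only constant and
#' the evidence. Parameters outside the prior support give `-Inf` rather
#' than an error, so samplers can treat them as auto-rejected states.
#'
#' @param params Model parameters.
#' @param curve A [sas_curve()].
#' @param beta Inverse temperature in `[0, 1]`.
#' @param priors A [prior_set()].
#' @return Scalar (possibly `-Inf`).
#' @export
log_posterior_unnorm <- function(params, curve, beta, priors) {
  if (length(beta) != 1L || is.na(beta) || beta < 0 || beta > 1)
    stop("beta must be a scalar in [0, 1]")
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(-Inf)
  if (beta == 0) return(lp)
  -beta * curve$N * poisson_cost(params, curve) + lp
}
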