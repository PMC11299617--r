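# Point estimates and posterior summaries from the beta = 1 replica.

#' MAP estimate from the posterior trace
#'
#' Returns the retained `beta = 1` sample maximizing the unnormalized log
#' posterior \eqn{-N E(\Xi) + \log\varphi(\Xi)}; ties are broken by the
#' earliest sweep. With replica exchange feeding the posterior replica from
#' a ladder that reaches the prior, this is a global rather than local
#' point estimate.
#'
#' @param chain An `remc_chain` from [run_remc()].
#' @return The MAP parameter object (`sphere_params` or `flat_params`) with
#'   attributes `log_posterior` and `sweep` (its index in the trace).
#' @export
map_estimate <- function(chain) {
  stopifnot(inherits(chain, "remc_chain"))
  L <- length(chain$betas)
  lp <- -chain$N * chain$E[, L] + chain$logprior[, L]
  i <- which.max(lp)
  params <- vec_to_params(replica_trace(chain)[i, ], chain$K)
  attr(params, "log_posterior") <- lp[i]
  attr(params, "sweep") <- i
  params
}

#' Poisson-standardized residuals
#'
#' \deqn{\Delta_i = \frac{y_i - T I(q_i, \Xi)}{\sqrt{T I(q_i, \Xi)}}.}
#' Under the Poisson observation model with the true parameters, the
#' residuals have mean 0 and variance approximately 1 at every point, so
#' systematic structure in \eqn{\Delta} exposes model misfit on a common
#' scale across the whole curve.
#'
#' @param params Model parameters.
#' @param curve A [sas_curve()].
#' @return Numeric vector of N standardized residuals.
#' @export
scattering_residuals <- function(params, curve) {
  stopifnot(inherits(curve, "sas_curve"))
  lambda <- curve$T * intensity(params, curve$q)
  (curve$y - lambda) / sqrt(lambda)
}

#' Posterior fit-curve envelope
#'
#' Evaluates the model intensity at `n_draws` parameter vectors sampled
#' uniformly without replacement from the retained `beta = 1` trace, and
#' summarizes them as per-q quantile bands. The spread of the band reflects
#' the posterior uncertainty of the fitted curve at each point.
#'
#' @param chain An `remc_chain`.
#' @param q Evaluation grid; defaults to the fitted curve's own grid.
#' @param n_draws Number of posterior draws (at most the trace length).
#' @param probs Quantiles for the bands.
#' @param seed Optional integer seed for the subsampling.
#' @return List with `q`, `bands` (length(q) x length(probs) matrix of
#'   intensity quantiles, columns named by probability) and `draws` (the
#'   n_draws x length(q) matrix of sampled curves).
#' @export
posterior_curve_envelope <- function(chain, q = NULL, n_draws = 1000L,
                                     probs = c(0.05, 0.5, 0.95), seed = NULL) {
  stopifnot(inherits(chain, "remc_chain"))
  if (is.null(q)) q <- chain$curve$q
  q <- check_qgrid(q)
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L || n_draws > chain$n_samples)
    stop("n_draws must be between 1 and the trace length")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- replica_trace(chain)
  idx <- sample.int(chain$n_samples, n_draws)
  draws <- t(vapply(idx, function(i) {
    intensity(vec_to_params(tr[i, ], chain$K), q)
  }, numeric(length(q))))
  bands <- t(apply(draws, 2L, quantile, probs = probs, names = FALSE))
  colnames(bands) <- sprintf("q%g", probs)
  list(q = q, bands = bands, draws = draws)
}

#' Equal-tailed posterior credible intervals
#'
#' @param chain An `remc_chain`.
#' @param level Credibility level (default 0.95).
#' @return Matrix with one row per parameter and columns `lower`, `median`,
#'   `upper`.
#' @export
credible_intervals <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "remc_chain"))
  a <- (1 - level) / 2
  tr <- replica_trace(chain)
  out <- t(apply(tr, 2L, quantile, probs = c(a, 0.5, 1 - a), names = FALSE))
  colnames(out) <- c("lower", "median", "upper")
  out
}
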