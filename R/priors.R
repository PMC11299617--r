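# Prior distributions: independent Gammas for radii, scales and background,
# a discrete uniform prior over the candidate component numbers K, and
# sampling/density evaluation on the ordered-radius parameterization.

#' Gamma prior specification
#'
#' @param shape,scale Positive shape and scale of a Gamma distribution
#'   (mean = shape * scale).
#' @return An object of class `gamma_prior`.
#' @export
gamma_prior <- function(shape, scale) {
  shape <- as.double(shape); scale <- as.double(scale)
  if (length(shape) != 1L || length(scale) != 1L || anyNA(c(shape, scale)) ||
      shape <= 0 || scale <= 0)
    stop("shape and scale must be positive scalars")
  structure(list(shape = shape, scale = scale), class = "gamma_prior")
}

#' Prior set for sphere-mixture model selection
#'
#' Independent Gamma priors for every radius, every scale parameter and the
#' background, plus a discrete uniform prior over the candidate K values.
#' The defaults are broad, weakly informative priors whose support covers
#' the regimes a two-component benchmark specimen can occupy: radii of a few
#' tenths to tens of nm, scale parameters spanning several decades, and a
#' background that may have to absorb the near-constant scattering of a very
#' small component. They should be adapted to the instrument and specimen at
#' hand, ideally after preliminary tests on synthetic data with noise and
#' parameter magnitudes similar to the measurement.
#'
#' @param prior_R,prior_S,prior_B [gamma_prior()] objects for radii, scales
#'   and background.
#' @param K_support Integer vector of candidate component numbers.
#' @return An object of class `prior_set`.
#' @examples
#' default_priors()
#' @export
prior_set <- function(prior_R = gamma_prior(2, 5),
                      prior_S = gamma_prior(2, 100),
                      prior_B = gamma_prior(1, 100),
                      K_support = 1:4) {
  stopifnot(inherits(prior_R, "gamma_prior"), inherits(prior_S, "gamma_prior"),
            inherits(prior_B, "gamma_prior"))
  K_support <- sort(unique(as.integer(K_support)))
  if (length(K_support) < 1L || any(K_support < 0))
    stop("K_support must contain non-negative integers")
  structure(list(prior_R = prior_R, prior_S = prior_S, prior_B = prior_B,
                 K_support = K_support),
            class = "prior_set")
}

#' @rdname prior_set
#' @export
default_priors <- function() prior_set()

#' Log prior density of model parameters
#'
#' Sum of independent Gamma log-densities over all radii, scale parameters
#' and the background. For sphere mixtures the density is defined on the
#' ordered-radius region (R non-increasing) and carries the `log(K!)`
#' normalization of the order statistics, so it integrates to one there and
#' the resulting evidence equals that of the exchangeable (unordered) prior.
#' Returns `-Inf` for parameters outside the support.
#'
#' @param params `sphere_params` or `flat_params`.
#' @param priors A [prior_set()].
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors) {
  stopifnot(inherits(priors, "prior_set"))
  if (inherits(params, "flat_params")) {
    return(dgamma(params$B, shape = priors$prior_B$shape,
                  scale = priors$prior_B$scale, log = TRUE))
  }
  stopifnot(inherits(params, "sphere_params"))
  if (any(params$R <= 0) || any(params$S <= 0) || params$B <= 0) return(-Inf)
  if (is.unsorted(rev(params$R))) return(-Inf)
  sum(dgamma(params$R, shape = priors$prior_R$shape,
             scale = priors$prior_R$scale, log = TRUE)) +
    sum(dgamma(params$S, shape = priors$prior_S$shape,
               scale = priors$prior_S$scale, log = TRUE)) +
    dgamma(params$B, shape = priors$prior_B$shape,
           scale = priors$prior_B$scale, log = TRUE) +
    lgamma(params$K + 1)
}

#' Draw model parameters from the prior
#'
#' Independent Gamma draws for each radius, scale and the background; radii
#' are then sorted in non-increasing order (with their scales carried along),
#' which is exactly a draw from the ordered prior used by the sampler.
#'
#' @param priors A [prior_set()].
#' @param K Number of components; `0` gives a [flat_params()] draw.
#' @param n Number of draws.
#' @return For `n = 1` a single parameter object, otherwise a list of them.
#' @export
sample_prior <- function(priors, K, n = 1L) {
  stopifnot(inherits(priors, "prior_set"))
  K <- as.integer(K); n <- as.integer(n)
  if (K < 0L || n < 1L) stop("K must be >= 0 and n >= 1")
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    B <- rgamma(1, shape = priors$prior_B$shape, scale = priors$prior_B$scale)
    if (K == 0L) {
      draws[[i]] <- flat_params(B)
    } else {
      R <- rgamma(K, shape = priors$prior_R$shape, scale = priors$prior_R$scale)
      S <- rgamma(K, shape = priors$prior_S$shape, scale = priors$prior_S$scale)
      draws[[i]] <- sphere_params(R, S, B)  # constructor sorts by radius
    }
  }
  if (n == 1L) draws[[1L]] else draws
}

#' Log prior probability of a candidate model
#'
#' Discrete uniform over `priors$K_support`: `-log(length(K_support))` inside
#' the support, `-Inf` outside.
#'
#' @param K Integer candidate component number.
#' @param priors A [prior_set()].
#' @return Scalar log probability.
#' @export
log_model_prior <- function(K, priors) {
  stopifnot(inherits(priors, "prior_set"))
  ifelse(as.integer(K) %in% priors$K_support,
         -log(length(priors$K_support)), -Inf)
}

# shape/scale triplets in the order the C++ core expects (R, S, B)
prior_shapes <- function(priors)
  c(priors$prior_R$shape, priors$prior_S$shape, priors$prior_B$shape)
prior_scales <- function(priors)
  c(priors$prior_R$scale, priors$prior_S$scale, priors$prior_B$scale)
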