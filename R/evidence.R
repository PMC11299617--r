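# Marginal likelihood, Bayesian free energy and posterior model probabilities.

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Log marginal likelihood from a replica-exchange run
#'
#' Stepping-stone (default): the evidence at `beta = 1` is the telescoping
#' product over adjacent rungs,
#' \deqn{\log Z = \sum_{l=1}^{L-1} \log \left\langle
#'   e^{-(\beta_{l+1}-\beta_l) N E(\Xi)} \right\rangle_{\beta_l},}
#' each expectation taken over the retained trace at \eqn{\beta_l} and
#' computed with max-shift (log-sum-exp) stabilization. The ladder must
#' start at `beta = 0`, where Z = 1 exactly, so the telescope is anchored.
#' `method = "ti"` instead applies trapezoidal thermodynamic integration of
#' \eqn{\langle N E \rangle_\beta} over the ladder; the two estimators agree
#' within Monte Carlo error on converged chains and their difference is a
#' useful ladder-resolution diagnostic.
#'
#' The value omits the data-only constant \eqn{-\sum_i \log y_i!}, which is
#' shared by all candidate models and cancels from model probabilities; set
#' `include_data_constant = TRUE` to add it back.
#'
#' @param chain An `remc_chain` from [run_remc()].
#' @param method `"stepping_stone"` or `"ti"`.
#' @param include_data_constant Add \eqn{-\sum \log y_i!} to the result.
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(chain,
                                    method = c("stepping_stone", "ti"),
                                    include_data_constant = FALSE) {
  stopifnot(inherits(chain, "remc_chain"))
  method <- match.arg(method)
  betas <- chain$betas
  if (betas[1L] != 0) stop("ladder must start at beta = 0 (telescope unanchored)")
  L <- length(betas)
  NE <- chain$N * chain$E  # n_samples x L matrix of N * E values
  logZ <- if (method == "stepping_stone") {
    terms <- vapply(seq_len(L - 1L), function(l) {
      log_mean_exp(-(betas[l + 1L] - betas[l]) * NE[, l])
    }, numeric(1))
    sum(terms)
  } else {
    mNE <- colMeans(NE)
    -sum(diff(betas) * (mNE[-L] + mNE[-1L]) / 2)
  }
  if (include_data_constant) logZ <- logZ + log_data_constant(chain$curve)
  logZ
}

#' Posterior model probabilities from free energies
#'
#' \deqn{P(K \mid D) = \frac{e^{-F(K)}\varphi(K)}{\sum_{K'} e^{-F(K')}\varphi(K')}}
#' computed with max-shift, so the result is invariant to adding any common
#' constant to all free energies (which is why dropping the shared data
#' constant from F is harmless).
#'
#' @param F Named or unnamed numeric vector of Bayesian free energies
#'   \eqn{F(K) = -\log Z(K)}, one per candidate model.
#' @param log_model_prior Vector of log prior model probabilities (defaults
#'   to uniform over the candidates).
#' @return Probability vector summing to one, names preserved.
#' @export
model_posterior <- function(F, log_model_prior = NULL) {
  if (!is.numeric(F) || length(F) < 1L) stop("F must be a numeric vector")
  if (all(!is.finite(-F))) stop("all free energies are infinite")
  if (is.null(log_model_prior)) log_model_prior <- rep(0, length(F))
  if (length(log_model_prior) != length(F))
    stop("log_model_prior must match F in length")
  w <- -F + log_model_prior
  m <- max(w)
  p <- exp(w - m)
  p <- p / sum(p)
  names(p) <- names(F)
  p
}

#' Monte Carlo standard error of the stepping-stone log evidence
#'
#' Moving-block bootstrap over each replica's retained trace: the per-rung
#' stepping-stone terms are recomputed on block-resampled traces (blocks
#' preserve the chain's short-range autocorrelation) and the per-term and
#' total standard errors are returned. Terms at different rungs come from
#' different replicas and are treated as independent.
#'
#' @param chain An `remc_chain`.
#' @param n_boot Number of bootstrap replicates.
#' @param block_len Block length; default `ceiling(n_samples^(1/3))` capped
#'   at the trace length.
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return List with `se` (total), `se_terms` (per rung), `n_boot`,
#'   `block_len`, and `degenerate` (TRUE when `n_boot < 2`, in which case
#'   the SE is reported as 0 with a warning).
#' @export
evidence_mc_error <- function(chain, n_boot = 200L, block_len = NULL,
                              seed = NULL) {
  stopifnot(inherits(chain, "remc_chain"))
  n <- chain$n_samples
  if (is.null(block_len)) block_len <- max(1L, ceiling(n^(1 / 3)))
  block_len <- as.integer(block_len)
  if (block_len > n) stop("trace shorter than bootstrap block")
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) {
    warning("n_boot < 2: degenerate bootstrap, SE reported as 0")
    return(list(se = 0, se_terms = rep(0, length(chain$betas) - 1L),
                n_boot = n_boot, block_len = block_len, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  betas <- chain$betas
  L <- length(betas)
  NE <- chain$N * chain$E
  n_blocks <- ceiling(n / block_len)
  se_terms <- vapply(seq_len(L - 1L), function(l) {
    w <- -(betas[l + 1L] - betas[l]) * NE[, l]
    if (max(w) == min(w)) return(0)
    reps <- vapply(seq_len(n_boot), function(b) {
      starts <- sample.int(n - block_len + 1L, n_blocks, replace = TRUE)
      idx <- as.vector(outer(seq_len(block_len) - 1L, starts, `+`))[seq_len(n)]
      log_mean_exp(w[idx])
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  list(se = sqrt(sum(se_terms^2)), se_terms = se_terms,
       n_boot = n_boot, block_len = block_len, degenerate = FALSE)
}
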