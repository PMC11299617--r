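# Replica-exchange Monte Carlo: temperature ladder, the main sampling driver,
# and single-step entry points (one Metropolis sweep, one exchange round) that
# run through the same compiled core as the full sampler.

#' Inverse-temperature ladder
#'
#' Builds the ladder \eqn{0 = \beta_1 < \beta_2 < \dots < \beta_L = 1}:
#' \eqn{\beta_1 = 0} (the prior, which anchors the evidence telescope at
#' Z = 1), then geometric spacing from `beta_min` up to 1. Geometric spacing
#' approximately equalizes both the exchange rates and the variance of the
#' stepping-stone terms when the tempered posteriors are close to their
#' large-count quadratic regime. `beta_min` must be small enough that the
#' prior-to-first-rung stepping stone is well estimated; with count levels up
#' to ~1e6 the prior spread of \eqn{N E} is of order 1e7 to 1e8, hence the
#' conservative default of 1e-9.
#'
#' @param L Number of replicas (at least 3).
#' @param beta_min Smallest positive inverse temperature.
#' @return Increasing numeric vector of length `L`, first element 0, last 1.
#' @examples
#' temperature_ladder(8, beta_min = 1e-4)
#' @export
temperature_ladder <- function(L = 32L, beta_min = 1e-9) {
  L <- as.integer(L)
  if (L < 3L) stop("L must be at least 3")
  if (!(beta_min > 0) || beta_min >= 1) stop("beta_min must be in (0, 1)")
  betas <- c(0, exp(seq(log(beta_min), 0, length.out = L - 1L)))
  betas[L] <- 1
  betas
}

check_ladder <- function(betas) {
  if (!is.numeric(betas) || length(betas) < 2L || anyNA(betas))
    stop("ladder must be a numeric vector of length >= 2")
  if (any(diff(betas) <= 0)) stop("ladder must be strictly increasing")
  if (betas[length(betas)] != 1) stop("ladder must end at beta = 1")
  as.double(betas)
}

par_vector <- function(params) {
  if (inherits(params, "flat_params")) return(params$B)
  c(params$R, params$S, params$B)
}

par_names <- function(K) {
  if (K == 0L) return("B")
  c(paste0("R", seq_len(K)), paste0("S", seq_len(K)), "B")
}

vec_to_params <- function(v, K) {
  if (K == 0L) return(flat_params(v[1L]))
  sphere_params(v[seq_len(K)], v[K + seq_len(K)], v[2L * K + 1L])
}

init_matrix <- function(priors, K, L) {
  P <- if (K == 0L) 1L else 2L * K + 1L
  m <- matrix(0, L, P)
  for (l in seq_len(L)) m[l, ] <- par_vector(sample_prior(priors, K))
  m
}

#' Run replica-exchange Monte Carlo for one candidate model
#'
#' Runs `n_burn` discarded sweeps followed by `n_samples` retained sweeps of
#' single-parameter Metropolis updates at every rung of the ladder, with
#' neighbor state exchanges every `exchange_interval` sweeps (alternating
#' even/odd pairs). Proposals are multiplicative (random walk on the log
#' scale), which respects positivity without boundary rejections; the
#' Jacobian is part of the acceptance ratio. Step sizes are adapted toward
#' `target_accept` during burn-in only and frozen afterwards, so the
#' retained phase satisfies detailed balance exactly. Radius proposals that
#' would break the non-increasing ordering are rejected, which confines each
#' chain to the ordered region the prior is defined on.
#'
#' @param curve A [sas_curve()].
#' @param K Number of sphere components (`0` = flat-background model).
#' @param priors A [prior_set()].
#' @param ladder Inverse-temperature ladder from [temperature_ladder()].
#' @param n_burn,n_samples Discarded and retained sweep counts.
#' @param exchange_interval Sweeps between exchange rounds (1 = every sweep).
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   run (initialization included) is exactly reproducible.
#' @param adapt Adapt step sizes during burn-in.
#' @param target_accept Metropolis acceptance-rate target for adaptation.
#' @param step_init Initial log-scale proposal standard deviation (scalar or
#'   L x P matrix).
#' @param init Optional L x P matrix of initial parameter vectors
#'   (rows = replicas, columns `R1..RK, S1..SK, B`); defaults to independent
#'   prior draws.
#' @return An object of class `remc_chain`: parameter traces
#'   (`n_samples` x P x L array), per-replica cost (`E`) and log-prior
#'   traces, the chi-squared trace of the `beta = 1` replica, acceptance and
#'   exchange diagnostics, final step sizes and the run configuration.
#' @export
run_remc <- function(curve, K, priors = default_priors(),
                     ladder = temperature_ladder(),
                     n_burn = 10000L, n_samples = 10000L,
                     exchange_interval = 1L, seed = NULL,
                     adapt = TRUE, target_accept = 0.3,
                     step_init = 0.5, init = NULL) {
  stopifnot(inherits(curve, "sas_curve"), inherits(priors, "prior_set"))
  K <- as.integer(K)
  if (K < 0L) stop("K must be non-negative")
  betas <- check_ladder(ladder)
  if (betas[1L] != 0) stop("ladder must start at beta = 0 to anchor the evidence telescope")
  n_burn <- as.integer(n_burn); n_samples <- as.integer(n_samples)
  if (n_burn < 0L || n_samples < 1L) stop("need n_burn >= 0 and n_samples >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- length(betas)
  P <- if (K == 0L) 1L else 2L * K + 1L
  if (is.null(init)) init <- init_matrix(priors, K, L)
  init <- as.matrix(init)
  if (!all(dim(init) == c(L, P))) stop("init must be an L x P matrix")
  step <- if (is.matrix(step_init)) step_init else matrix(step_init, L, P)

  out <- .remc_core_cpp(curve$q, curve$y, curve$T, K,
                        prior_shapes(priors), prior_scales(priors),
                        betas, init, step,
                        n_burn, n_samples, as.integer(exchange_interval), 0L,
                        TRUE, isTRUE(adapt), target_accept, TRUE)

  if (any(!is.finite(out$E)))
    stop("non-finite cost encountered during sampling")
  acc_rate <- out$acc / pmax(out$prop, 1L)
  exch_rate <- out$exch_acc / pmax(out$exch_att, 1L)
  structure(list(
    trace = out$trace, E = out$E, logprior = out$logprior, chi2 = out$chi2,
    betas = betas, K = K, P = P, par_names = par_names(K),
    N = curve$N, T = curve$T, curve = curve, priors = priors,
    n_burn = n_burn, n_samples = n_samples,
    exchange_interval = as.integer(exchange_interval),
    acc_rate = acc_rate, exch_rate = exch_rate, exch_att = out$exch_att,
    final_step = out$final_step, seed = seed), class = "remc_chain")
}

#' @export
print.remc_chain <- function(x, ...) {
  cat(sprintf("REMC chain: K = %d, L = %d replicas, %d retained sweeps (burn-in %d)\n",
              x$K, length(x$betas), x$n_samples, x$n_burn))
  cat(sprintf("  Metropolis acceptance (beta = 1): %s\n",
              paste(sprintf("%s %.2f", x$par_names,
                            x$acc_rate[length(x$betas), ]), collapse = ", ")))
  cat(sprintf("  exchange acceptance: %.2f-%.2f (median %.2f)\n",
              min(x$exch_rate), max(x$exch_rate),
              stats::median(x$exch_rate)))
  invisible(x)
}

#' One Metropolis sweep over all replicas
#'
#' Advances every replica by one sweep of single-parameter Metropolis
#' updates (no exchanges, no adaptation), using the same compiled kernel as
#' [run_remc()]. Useful for unit-level verification of the update rule.
#'
#' @param state L x P matrix of current parameter vectors (rows = replicas).
#' @param curve,priors,ladder As in [run_remc()].
#' @param step_sizes Scalar or L x P matrix of proposal standard deviations.
#' @param n_sweeps Number of sweeps to advance.
#' @return List with `params` (updated L x P matrix), per-replica `E` and
#'   `logprior`, and the acceptance counts of the last `n_sweeps` sweeps.
#' @export
metropolis_sweep <- function(state, curve, priors, ladder, step_sizes = 0.5,
                             n_sweeps = 1L) {
  betas <- check_ladder(ladder)
  state <- as.matrix(state)
  L <- length(betas); P <- ncol(state)
  K <- if (P == 1L) 0L else (P - 1L) %/% 2L
  step <- if (is.matrix(step_sizes)) step_sizes else matrix(step_sizes, L, P)
  out <- .remc_core_cpp(curve$q, curve$y, curve$T, K,
                        prior_shapes(priors), prior_scales(priors),
                        betas, state, step,
                        0L, as.integer(n_sweeps), 0L, 0L,
                        TRUE, FALSE, 0.3, FALSE)
  list(params = out$final_params, E = out$final_E,
       logprior = out$final_logprior,
       accepted = out$acc, proposed = out$prop)
}

#' One round of replica exchanges
#'
#' Attempts swaps between adjacent pairs `(l, l+1)` with `l` of the given
#' parity, accepting with probability
#' \eqn{\min\{1, \exp[N(\beta_{l+1}-\beta_l)(E_{l+1}-E_l)]\}} (the prior
#' terms cancel because both replicas share the same prior).
#'
#' @param state L x P matrix of current parameter vectors.
#' @param curve A [sas_curve()].
#' @param ladder Inverse-temperature ladder.
#' @param parity `"even"` attempts pairs (1,2), (3,4), ...; `"odd"` attempts
#'   (2,3), (4,5), ...
#' @param priors A [prior_set()] (only needed to evaluate the log prior of
#'   the returned state).
#' @return List with `params`, `E`, `logprior`, `swapped` (attempt and
#'   acceptance counts per adjacent pair).
#' @export
exchange_step <- function(state, curve, ladder, parity = c("even", "odd"),
                          priors = default_priors()) {
  parity <- match.arg(parity)
  betas <- check_ladder(ladder)
  state <- as.matrix(state)
  L <- length(betas); P <- ncol(state)
  K <- if (P == 1L) 0L else (P - 1L) %/% 2L
  step <- matrix(0.5, L, P)
  out <- .remc_core_cpp(curve$q, curve$y, curve$T, K,
                        prior_shapes(priors), prior_scales(priors),
                        betas, state, step,
                        0L, 1L, 1L, if (parity == "even") 0L else 1L,
                        FALSE, FALSE, 0.3, FALSE)
  list(params = out$final_params, E = out$final_E,
       logprior = out$final_logprior,
       swapped = list(attempted = out$exch_att, accepted = out$exch_acc))
}

#' Tune Metropolis step sizes with an adaptive pilot run
#'
#' Runs a short pilot with Robbins-Monro adaptation of every per-replica,
#' per-parameter log step size toward `target_accept`, and returns the
#' frozen step-size matrix. [run_remc()] performs the same adaptation during
#' its own burn-in, so an explicit pilot is only needed when the adapted
#' steps are to be inspected or reused across runs.
#'
#' @param curve,K,priors,ladder As in [run_remc()].
#' @param n_pilot Number of adaptation sweeps.
#' @param target_accept Target Metropolis acceptance rate.
#' @param step_init Initial step size.
#' @param seed Optional integer seed.
#' @return L x P matrix of tuned proposal standard deviations.
#' @export
tune_step_sizes <- function(curve, K, priors = default_priors(),
                            ladder = temperature_ladder(),
                            n_pilot = 2000L, target_accept = 0.3,
                            step_init = 0.5, seed = NULL) {
  betas <- check_ladder(ladder)
  if (!is.null(seed)) set.seed(as.integer(seed))
  K <- as.integer(K)
  L <- length(betas)
  P <- if (K == 0L) 1L else 2L * K + 1L
  init <- init_matrix(priors, K, L)
  step <- matrix(step_init, L, P)
  out <- .remc_core_cpp(curve$q, curve$y, curve$T, K,
                        prior_shapes(priors), prior_scales(priors),
                        betas, init, step,
                        as.integer(n_pilot), 1L, 1L, 0L,
                        TRUE, TRUE, target_accept, FALSE)
  out$final_step
}

#' Extract the retained trace of one replica
#'
#' @param chain An `remc_chain`.
#' @param beta_index Replica index (default the `beta = 1` posterior replica).
#' @return Matrix `n_samples` x P with named columns.
#' @export
replica_trace <- function(chain, beta_index = length(chain$betas)) {
  stopifnot(inherits(chain, "remc_chain"))
  m <- chain$trace[, , beta_index, drop = FALSE]
  dim(m) <- dim(chain$trace)[1:2]
  colnames(m) <- chain$par_names
  m
}
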