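# End-to-end orchestration: per-curve model selection across candidate K,
# and sweeps over scenario grids with per-seed tallies.

#' Sampler configuration
#'
#' Collects the REMC settings shared by all runs of an experiment. `scale`
#' multiplies the sweep counts (`scale = 0.1` is a quick desk mode); the
#' replica count is left untouched because the ladder resolution, not the
#' trace length, controls the stepping-stone bias.
#'
#' @param L Number of replicas.
#' @param beta_min Smallest positive inverse temperature.
#' @param n_burn,n_samples Burn-in and retained sweeps (before scaling).
#' @param exchange_interval Sweeps between exchange rounds.
#' @param target_accept Metropolis acceptance target for adaptation.
#' @param scale Multiplier applied to `n_burn` and `n_samples`.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(L = 32L, beta_min = 1e-9,
                           n_burn = 1e5, n_samples = 1e5,
                           exchange_interval = 1L, target_accept = 0.3,
                           scale = 1) {
  structure(list(L = as.integer(L), beta_min = beta_min,
                 n_burn = max(1L, as.integer(round(n_burn * scale))),
                 n_samples = max(2L, as.integer(round(n_samples * scale))),
                 exchange_interval = as.integer(exchange_interval),
                 target_accept = target_accept),
            class = "sampler_config")
}

#' Bayesian model selection for one scattering curve
#'
#' Runs replica-exchange MC for every candidate K, estimates each marginal
#' likelihood by stepping stone, converts free energies to posterior model
#' probabilities under the model prior, and attaches the MAP estimate and
#' the reduced chi-squared baseline. Fully deterministic given `seed`.
#'
#' @param curve A [sas_curve()].
#' @param candidate_K Integer vector of candidate component numbers.
#' @param priors A [prior_set()]; its `K_support` supplies the model prior
#'   weights for the candidates.
#' @param config A [sampler_config()].
#' @param seed Integer seed; per-K run seeds are derived from it.
#' @param keep_chains Keep the full `remc_chain` objects in the result.
#' @return An object of class `model_selection`: vectors `K`, `logZ`, `F`,
#'   `P`, `selected_K`, per-K MAP parameters, the chi-squared baseline
#'   (`chi2`), and sampler diagnostics.
#' @export
run_model_selection <- function(curve, candidate_K = 1:4,
                                priors = default_priors(),
                                config = sampler_config(),
                                seed = 1L, keep_chains = FALSE) {
  stopifnot(inherits(curve, "sas_curve"), inherits(config, "sampler_config"))
  candidate_K <- sort(unique(as.integer(candidate_K)))
  if (length(candidate_K) < 1L) stop("candidate_K must be non-empty")
  ladder <- temperature_ladder(config$L, config$beta_min)
  chains <- vector("list", length(candidate_K))
  names(chains) <- paste0("K", candidate_K)
  for (i in seq_along(candidate_K)) {
    chains[[i]] <- run_remc(curve, candidate_K[i], priors, ladder,
                            n_burn = config$n_burn,
                            n_samples = config$n_samples,
                            exchange_interval = config$exchange_interval,
                            seed = as.integer(seed) * 101L + candidate_K[i],
                            target_accept = config$target_accept)
  }
  logZ <- vapply(chains, log_marginal_likelihood, numeric(1))
  F <- -logZ
  lpK <- vapply(candidate_K, log_model_prior, numeric(1), priors = priors)
  P <- model_posterior(F, lpK)
  maps <- lapply(chains, map_estimate)
  chi2 <- select_by_chi2(chains)
  diagnostics <- lapply(chains, function(ch) {
    list(exch_rate = ch$exch_rate,
         acc_rate_posterior = ch$acc_rate[length(ch$betas), ],
         mean_E = colMeans(ch$E))
  })
  structure(list(K = candidate_K, logZ = logZ, F = F, P = P,
                 selected_K = candidate_K[which.max(P)],
                 map = maps, chi2 = chi2, diagnostics = diagnostics,
                 seed = as.integer(seed),
                 config = unclass(config),
                 chains = if (keep_chains) chains else NULL),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Bayesian model selection over K =", paste(x$K, collapse = ", "), "\n")
  tab <- data.frame(K = x$K, F = x$F, P = round(x$P, 4),
                    chi2_reduced = round(x$chi2$chi2_reduced, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("selected (posterior): K = %d;  selected (chi-squared): K = %d\n",
              x$selected_K, x$chi2$selected_K))
  invisible(x)
}

#' Scenario sweep with per-seed selection tallies
#'
#' For each scenario and each of its data seeds, generates a synthetic
#' curve, runs [run_model_selection()], and records which K wins under the
#' Bayesian selector and under the reduced chi-squared baseline. Any failed
#' run is recorded with `NA` selections rather than dropped.
#'
#' @param scenarios List of [scenario()] objects.
#' @param candidate_K Candidate component numbers.
#' @param priors,config As in [run_model_selection()].
#' @param seed Base integer seed for the samplers (data seeds come from each
#'   scenario's own seed list).
#' @return An object of class `sweep_result`: `runs`, a data frame with one
#'   row per scenario x seed (winning K, posterior probabilities, reduced
#'   chi-squared values), and `tally`, the per-scenario count of wins per K.
#' @export
run_sweep <- function(scenarios, candidate_K = 1:4,
                      priors = default_priors(),
                      config = sampler_config(), seed = 1L) {
  if (inherits(scenarios, "sas_scenario")) scenarios <- list(scenarios)
  if (!is.list(scenarios) || length(scenarios) < 1L ||
      !all(vapply(scenarios, inherits, logical(1), "sas_scenario")))
    stop("scenarios must be one or more sas_scenario objects")
  rows <- list()
  run_id <- 0L
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    for (ds in scen$seeds) {
      run_id <- run_id + 1L
      res <- tryCatch({
        curve <- generate_curve(scen, ds)
        run_model_selection(curve, candidate_K, priors, config,
                            seed = as.integer(seed) + 1000L * run_id)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[run_id]] <- data.frame(
          scenario = scen$label, r_S = scen$r_S, r_R = scen$r_R, T = scen$T,
          data_seed = ds, selected_K = NA_integer_,
          chi2_selected_K = NA_integer_, error = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        row <- data.frame(
          scenario = scen$label, r_S = scen$r_S, r_R = scen$r_R, T = scen$T,
          data_seed = ds, selected_K = res$selected_K,
          chi2_selected_K = res$chi2$selected_K, error = NA_character_,
          stringsAsFactors = FALSE)
        for (i in seq_along(res$K)) {
          row[[sprintf("P_K%d", res$K[i])]] <- unname(res$P[i])
          row[[sprintf("chi2red_K%d", res$K[i])]] <- res$chi2$chi2_reduced[i]
        }
        rows[[run_id]] <- row
      }
    }
  }
  runs <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (m in miss) r[[m]] <- NA
    r
  }))
  tally <- tally_sweep(runs, candidate_K)
  structure(list(runs = runs, tally = tally, candidate_K = candidate_K,
                 seed = as.integer(seed), config = unclass(config)),
            class = "sweep_result")
}

tally_sweep <- function(runs, candidate_K, column = "selected_K") {
  labs <- unique(runs$scenario)
  out <- do.call(rbind, lapply(labs, function(lab) {
    sub <- runs[runs$scenario == lab, ]
    counts <- vapply(candidate_K,
                     function(k) sum(sub[[column]] == k, na.rm = TRUE),
                     integer(1))
    d <- data.frame(scenario = lab, r_S = sub$r_S[1L], r_R = sub$r_R[1L],
                    T = sub$T[1L], n_datasets = nrow(sub),
                    stringsAsFactors = FALSE)
    for (i in seq_along(candidate_K))
      d[[sprintf("K%d", candidate_K[i])]] <- counts[i]
    d
  }))
  out
}

#' Tally the chi-squared baseline selections of a sweep
#'
#' @param sweep A `sweep_result` from [run_sweep()].
#' @return Data frame shaped like `sweep$tally` but counting the reduced
#'   chi-squared winner per data set.
#' @export
chi2_tally <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  tally_sweep(sweep$runs, sweep$candidate_K, column = "chi2_selected_K")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Scenario sweep:", nrow(x$runs), "runs\n")
  print(x$tally, row.names = FALSE)
  invisible(x)
}
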