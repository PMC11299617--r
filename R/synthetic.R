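# Synthetic-data generation: Poisson-sampled curves from known sphere
# mixtures, and the two benchmark scenario grids (scale-ratio sweep and
# radius-ratio sweep) used throughout the package's experiments.

#' Benchmark scenario: known truth for synthetic-curve generation
#'
#' A scenario bundles the true generating parameters, the pseudo-measurement
#' time, the q grid and the list of data seeds. For two-component truths the
#' discriminability ratios are recorded: `r_S`, the scale of the larger
#' sphere relative to the smaller one, and `r_R`, the smaller radius over
#' the larger one. Both tend to 0 (and `r_R` also to 1) as the two
#' components become indistinguishable.
#'
#' @param params True generating parameters (`sphere_params`).
#' @param T Pseudo-measurement time.
#' @param N,qmin,qmax q grid specification (see [make_qgrid()]).
#' @param seeds Integer seeds, one synthetic data set per seed.
#' @param label Optional scenario label.
#' @return An object of class `sas_scenario`.
#' @export
scenario <- function(params, T = 1, N = 400L, qmin = 0.1, qmax = 3.0,
                     seeds = 0:9, label = NULL) {
  stopifnot(inherits(params, "sphere_params"))
  r_S <- r_R <- NA_real_
  if (params$K == 2L) {
    r_S <- params$S[1L] / params$S[2L]  # components sorted by radius desc
    r_R <- params$R[2L] / params$R[1L]
  }
  structure(list(params = params, T = as.double(T), N = as.integer(N),
                 qmin = qmin, qmax = qmax, seeds = as.integer(seeds),
                 r_S = r_S, r_R = r_R,
                 label = label %||% sprintf("K%d_T%g", params$K, T)),
            class = "sas_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sas_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: K = %d, T = %g, N = %d, q in [%g, %g]\n",
              x$label, x$params$K, x$T, x$N, x$qmin, x$qmax))
  if (!is.na(x$r_S)) cat(sprintf("  r_S = %g, r_R = %g\n", x$r_S, x$r_R))
  invisible(x)
}

#' Generate one synthetic scattering curve
#'
#' Evaluates the true model intensity on the scenario's q grid, scales by
#' the pseudo-measurement time, and draws each observation independently as
#' \eqn{y_i \sim \mathrm{Poisson}(T I(q_i, \Xi^*))}. Deterministic given
#' the seed.
#'
#' @param scen A [scenario()].
#' @param seed Integer seed for the Poisson draws.
#' @return A [sas_curve()].
#' @export
generate_curve <- function(scen, seed = 0L) {
  stopifnot(inherits(scen, "sas_scenario"))
  q <- make_qgrid(scen$N, scen$qmin, scen$qmax)
  lambda <- scen$T * intensity(scen$params, q)
  set.seed(as.integer(seed))
  sas_curve(q, rpois(length(q), lambda), T = scen$T)
}

#' Benchmark scenario grids
#'
#' `scale_ratio_scenarios()` builds the six two-component scenarios in which
#' the larger sphere (R = 10 nm) is progressively faded out: the smaller
#' sphere (R = 2 nm) keeps scale 250 while the larger sphere's scale runs
#' through 250, 100, 20, 0.5, 0.1 and 0.05, giving scale ratios
#' 1.0, 0.4, 0.08, 0.002, 0.0004 and 0.0002. `radius_ratio_scenarios()`
#' builds the seven scenarios in which one sphere's radius approaches, or
#' shrinks far below, the reference sphere (R = 10 nm, scale 100): the other
#' component has scale 250 and radius 9.9, 9.7, 9.5, 5, 0.5, 0.4 or 0.3 nm,
#' giving radius ratios 0.99, 0.97, 0.95, 0.5, 0.05, 0.04 and 0.03. Both
#' grids use background 0.01 and N = 400 points on q in [0.1, 3] nm^-1.
#'
#' @param T Pseudo-measurement time (1 or 0.1 in the benchmark study).
#' @param seeds Data seeds per scenario.
#' @return List of [scenario()] objects, named by ratio.
#' @export
scale_ratio_scenarios <- function(T = 1, seeds = 0:9) {
  S2 <- c(250, 100, 20, 0.5, 0.1, 0.05)
  lapply(stats::setNames(S2, sprintf("rS_%g", S2 / 250)), function(s2) {
    scenario(sphere_params(R = c(2, 10), S = c(250, s2), B = 0.01),
             T = T, seeds = seeds, label = sprintf("rS_%g_T%g", s2 / 250, T))
  })
}

#' @rdname scale_ratio_scenarios
#' @export
radius_ratio_scenarios <- function(T = 1, seeds = 0:9) {
  R1 <- c(9.9, 9.7, 9.5, 5, 0.5, 0.4, 0.3)
  lapply(stats::setNames(R1, sprintf("rR_%g", R1 / 10)), function(r1) {
    scenario(sphere_params(R = c(r1, 10), S = c(250, 100), B = 0.01),
             T = T, seeds = seeds, label = sprintf("rR_%g_T%g", r1 / 10, T))
  })
}
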