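# Conventional baseline: reduced chi-squared model selection.

#' Chi-squared error of a model on a curve
#'
#' Pearson chi-squared with Poisson variance,
#' \deqn{\chi^2 = \sum_i \frac{(y_i - T I(q_i,\Xi))^2}{T I(q_i,\Xi)},}
#' which equals the sum of squared Poisson-standardized residuals (see
#' [scattering_residuals()]). The model-mean denominator is consistent with
#' the Poisson generative model; `weighting = "data"` switches to the
#' data-weighted denominator `max(y_i, 1)` sometimes used in practice.
#'
#' @param params Model parameters.
#' @param curve A [sas_curve()].
#' @param weighting `"model"` (default) or `"data"`.
#' @return Scalar chi-squared.
#' @export
chi_squared <- function(params, curve, weighting = c("model", "data")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(curve, "sas_curve"))
  lambda <- curve$T * intensity(params, curve$q)
  den <- if (weighting == "model") lambda else pmax(curve$y, 1)
  sum((curve$y - lambda)^2 / den)
}

#' Reduced chi-squared
#'
#' Chi-squared divided by the degrees of freedom `N - (2K + 1)`: the number
#' of data points minus the number of free model parameters (K radii, K
#' scales, one background).
#'
#' @param chi2 Chi-squared value.
#' @param N Number of data points.
#' @param K Number of sphere components.
#' @return Scalar reduced chi-squared.
#' @export
reduced_chi_squared <- function(chi2, N, K) {
  dof <- as.integer(N) - (2L * as.integer(K) + 1L)
  if (dof <= 0L) stop("non-positive degrees of freedom: N must exceed 2K + 1")
  chi2 / dof
}

#' Model selection by reduced chi-squared
#'
#' The conventional selector: for each candidate K, minimize chi-squared
#' over the retained `beta = 1` posterior samples (a global search that
#' stands in for quasi-Newton fitting), divide by the degrees of freedom,
#' and pick the model whose reduced chi-squared is closest to 1 (ties go to
#' the smaller K).
#'
#' @param chains Named or unnamed list of `remc_chain` objects, one per
#'   candidate K.
#' @return List with `selected_K`, and per-candidate vectors `K`,
#'   `chi2_min`, `chi2_reduced`.
#' @export
select_by_chi2 <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1L)
  Ks <- vapply(chains, function(ch) ch$K, integer(1))
  chi2_min <- vapply(chains, function(ch) min(ch$chi2), numeric(1))
  chi2_red <- mapply(reduced_chi_squared, chi2_min,
                     vapply(chains, function(ch) ch$N, integer(1)), Ks)
  ord <- order(abs(chi2_red - 1), Ks)
  list(selected_K = Ks[ord[1L]], K = Ks, chi2_min = chi2_min,
       chi2_reduced = chi2_red)
}
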