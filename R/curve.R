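# The measured-data container: a 1-D scattering curve with count semantics.

#' Scattering curve with Poisson count semantics
#'
#' A measured (or simulated) small-angle scattering curve: q values,
#' observed intensities `y` treated as counts, and the pseudo-measurement
#' time `T` that links the model intensity to the Poisson mean,
#' \eqn{y_i \sim \mathrm{Poisson}(T \, I(q_i))}. Smaller `T` means noisier
#' data.
#'
#' @param q Strictly increasing positive scattering-vector magnitudes (nm^-1).
#' @param y Non-negative observed intensities (counts).
#' @param T Positive pseudo-measurement time (count-scale multiplier).
#' @return An object of class `sas_curve` with fields `q`, `y`, `T`, `N`.
#' @export
sas_curve <- function(q, y, T = 1) {
  q <- check_qgrid(q)
  y <- as.double(y)
  T <- as.double(T)
  if (length(y) != length(q)) stop("q and y must have equal length")
  if (anyNA(y) || any(y < 0)) stop("y must be non-negative")
  if (length(T) != 1L || is.na(T) || T <= 0) stop("T must be a positive scalar")
  structure(list(q = q, y = y, T = T, N = length(q)), class = "sas_curve")
}

#' @export
print.sas_curve <- function(x, ...) {
  cat(sprintf("Scattering curve: N = %d points, q in [%.4g, %.4g] nm^-1, T = %g\n",
              x$N, min(x$q), max(x$q), x$T))
  cat(sprintf("  counts: total %.4g, max %.4g, %d zero points\n",
              sum(x$y), max(x$y), sum(x$y == 0)))
  invisible(x)
}
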