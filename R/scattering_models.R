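# Forward models: scattering intensity of dilute mixtures of monodisperse
# spheres, plus a registry so other form factors can plug in behind the same
# intensity() contract.

#' Squared sphere form-factor amplitude
#'
#' Evaluates \eqn{\Phi(x)^2} with \eqn{\Phi(x) = 3(\sin x - x\cos x)/x^3},
#' the normalized scattering amplitude of a uniform sphere as a function of
#' the dimensionless product \eqn{x = qR}. \eqn{\Phi(0) = 1}; below
#' \eqn{x = 10^{-4}} a series expansion is used so the removable singularity
#' at the origin does not amplify floating-point cancellation.
#'
#' @param x Numeric vector of non-negative \eqn{qR} values.
#' @return Numeric vector of values in \eqn{[0, 1]}.
#' @examples
#' form_factor_sq(c(0, pi))  # 1 and (3/pi^2)^2
#' @export
form_factor_sq <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("x must be numeric without NAs")
  if (any(x < 0)) stop("x must be non-negative")
  .phi2_cpp(as.double(x))
}

#' Parameters of a K-component monodisperse-sphere mixture
#'
#' Bundles radii `R` (nm), normalized scale parameters `S` (one per
#' component) and a background intensity `B`. Components are stored sorted by
#' radius in non-increasing order; this fixes the labeling of components and
#' removes the permutation symmetry of the mixture.
#'
#' @param R Positive radii in nm (length K).
#' @param S Positive scale parameters (length K).
#' @param B Positive background intensity.
#' @return An object of class `sphere_params` with fields `K`, `R`, `S`, `B`.
#' @examples
#' sphere_params(R = c(2, 10), S = c(250, 100), B = 0.01)
#' @export
sphere_params <- function(R, S, B) {
  R <- as.double(R); S <- as.double(S); B <- as.double(B)
  if (length(R) < 1L || length(R) != length(S) || length(B) != 1L)
    stop("R and S must have equal positive length; B must be scalar")
  if (anyNA(c(R, S, B)) || any(R <= 0) || any(S <= 0) || B <= 0)
    stop("all parameters must be positive")
  ord <- order(R, decreasing = TRUE)
  structure(list(K = length(R), R = R[ord], S = S[ord], B = B),
            class = "sphere_params")
}

#' Flat-background model parameters
#'
#' The degenerate zero-component model `I(q) = B`. Mainly useful as the
#' simplest registered model and as a conjugate test bed for the sampler
#' (a constant Poisson mean with a Gamma prior has closed-form posterior
#' and evidence).
#'
#' @param B Positive background intensity.
#' @return An object of class `flat_params` with fields `K = 0`, `B`.
#' @export
flat_params <- function(B) {
  B <- as.double(B)
  if (length(B) != 1L || is.na(B) || B <= 0) stop("B must be a positive scalar")
  structure(list(K = 0L, B = B), class = "flat_params")
}

#' @export
print.sphere_params <- function(x, ...) {
  cat("Sphere mixture, K =", x$K, "components\n")
  cat("  R (nm):", format(x$R, digits = 4), "\n")
  cat("  S:     ", format(x$S, digits = 4), "\n")
  cat("  B:     ", format(x$B, digits = 4), "\n")
  invisible(x)
}

#' Evenly spaced scattering-vector grid
#'
#' @param N Number of points (at least 2).
#' @param qmin,qmax Grid endpoints in nm^-1, both included.
#' @return Numeric vector of strictly increasing q values.
#' @examples
#' q <- make_qgrid()          # 400 points on [0.1, 3]
#' @export
make_qgrid <- function(N = 400L, qmin = 0.1, qmax = 3.0) {
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2")
  if (!(qmin > 0) || qmax <= qmin) stop("need 0 < qmin < qmax")
  seq(qmin, qmax, length.out = N)
}

check_qgrid <- function(q) {
  if (!is.numeric(q) || length(q) < 1L || anyNA(q)) stop("q must be numeric without NAs")
  if (any(q <= 0)) stop("all q must be positive")
  if (length(q) > 1L && any(diff(q) <= 0)) stop("q must be strictly increasing")
  as.double(q)
}

#' Model scattering intensity
#'
#' For a sphere mixture the intensity at scattering-vector magnitude q is
#' \deqn{I_K(q) = \sum_{k=1}^K S_k V(R_k) \Phi(q R_k)^2 + B,}
#' with sphere volume \eqn{V(R) = 4\pi R^3/3} and \eqn{\Phi} the normalized
#' sphere amplitude (see [form_factor_sq()]). The scale parameters `S` are
#' the normalized per-component scales, proportional to contrast-squared
#' times volume fraction; the volume factor is kept explicit so that larger
#' spheres of equal `S` scatter more strongly, as they do physically.
#'
#' @param params A `sphere_params` or `flat_params` object (or any registered
#'   model's parameter object).
#' @param q Strictly increasing, positive q grid (nm^-1).
#' @return Vector of intensities, one per q, bounded below by `B`.
#' @examples
#' p <- sphere_params(R = c(2, 10), S = c(250, 100), B = 0.01)
#' intensity(p, make_qgrid(50))
#' @export
intensity <- function(params, q) UseMethod("intensity")

#' @export
intensity.sphere_params <- function(params, q) {
  q <- check_qgrid(q)
  I <- rep(params$B, length(q))
  for (k in seq_len(params$K)) {
    V <- 4 / 3 * pi * params$R[k]^3
    I <- I + params$S[k] * V * form_factor_sq(q * params$R[k])
  }
  I
}

#' @export
intensity.flat_params <- function(params, q) {
  q <- check_qgrid(q)
  rep(params$B, length(q))
}

# ---- model registry ---------------------------------------------------------

.sas_models <- new.env(parent = emptyenv())

#' Register a scattering model
#'
#' Models are keyed by name and must provide an `intensity(params, q)`
#' function and the number of free parameters as a function of K. The two
#' built-in entries are `"sphere_mixture"` and `"flat_background"`; new form
#' factors (cylinders, core-shell particles, ...) can be added behind the
#' same contract.
#'
#' @param name Model name (string key).
#' @param intensity_fn Function `(params, q) -> numeric`.
#' @param n_params Function `(K) -> integer`, number of free parameters.
#' @export
register_sas_model <- function(name, intensity_fn, n_params) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(intensity_fn), is.function(n_params))
  assign(name, list(intensity = intensity_fn, n_params = n_params),
         envir = .sas_models)
  invisible(name)
}

#' Look up a registered scattering model
#' @param name Model name.
#' @return List with elements `intensity` and `n_params`.
#' @export
get_sas_model <- function(name) {
  if (!exists(name, envir = .sas_models, inherits = FALSE))
    stop("unknown model: ", name, " (see list_sas_models())")
  get(name, envir = .sas_models, inherits = FALSE)
}

#' Names of registered scattering models
#' @return Character vector.
#' @export
list_sas_models <- function() sort(ls(envir = .sas_models))

register_builtin_models <- function() {
  register_sas_model("sphere_mixture",
                     intensity_fn = function(params, q) intensity(params, q),
                     n_params = function(K) 2L * as.integer(K) + 1L)
  register_sas_model("flat_background",
                     intensity_fn = function(params, q) intensity(params, q),
                     n_params = function(K) 1L)
}

.onLoad <- function(libname, pkgname) register_builtin_models()
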