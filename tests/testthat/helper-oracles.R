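# Independent oracles, written directly from closed forms and kept separate
# from the package implementation they check.

# Evidence of the flat-background model by conjugacy: y_i ~ Poisson(T*B),
# B ~ Gamma(a, scale s). With the y! factors dropped (the package's cost
# convention), Z = T^{sum y} * Gamma(a + sum y) / (Gamma(a) s^a) *
# (N T + 1/s)^-(a + sum y).
conjugate_log_evidence <- function(y, T, shape, scale) {
  N <- length(y)
  sy <- sum(y)
  sy * log(T) + lgamma(shape + sy) - lgamma(shape) - shape * log(scale) -
    (shape + sy) * log(N * T + 1 / scale)
}

# Conjugate posterior of B for the same model.
conjugate_posterior <- function(y, T, shape, scale) {
  list(shape = shape + sum(y), scale = 1 / (length(y) * T + 1 / scale))
}

# First positive zero of the sphere amplitude: root of tan x = x, bracketed
# away from the pole at pi/2.
sphere_amplitude_first_zero <- function() {
  uniroot(function(x) sin(x) - x * cos(x), c(pi, 3 * pi / 2),
          tol = 1e-12)$root
}
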