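# Shared fixtures: small, fast objects built in code at test time.

fast_ladder <- function(L = 8L, beta_min = 1e-6) temperature_ladder(L, beta_min)

# a small single-sphere scenario whose curves are cheap to fit
small_scenario <- function(T = 1, N = 60L, seeds = 0:9) {
  scenario(sphere_params(R = 5, S = 50, B = 0.5), T = T, N = N,
           qmin = 0.1, qmax = 3, seeds = seeds, label = "small_K1")
}

small_curve <- function(seed = 1L, ...) generate_curve(small_scenario(...), seed)

# a flat-background (constant Poisson mean) curve: the conjugate test bed
flat_curve <- function(N = 50L, B = 5, T = 1, seed = 42L) {
  q <- make_qgrid(N, 0.1, 3)
  set.seed(seed)
  sas_curve(q, rpois(N, T * B), T = T)
}

# settings used for the scenario-tally checks: small enough to keep the suite
# fast, large enough that the evidence ranking is stable (see the vignette)
tally_config <- function() sampler_config(L = 16L, beta_min = 1e-9,
                                          n_burn = 4000L, n_samples = 4000L)
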