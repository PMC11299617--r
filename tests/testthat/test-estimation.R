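test_that("MAP estimate is the trace argmax of the log posterior", {
  cur <- small_curve(1)
  ch <- run_remc(cur, 1, ladder = fast_ladder(6), n_burn = 500,
                 n_samples = 1000, seed = 4)
  m <- map_estimate(ch)
  L <- length(ch$betas)
  lp <- -ch$N * ch$E[, L] + ch$logprior[, L]
  expect_equal(attr(m, "log_posterior"), max(lp))
  expect_equal(attr(m, "sweep"), which.max(lp))
  # the MAP beats the posterior-mean parameter point
  pm <- vec_to_params(colMeans(replica_trace(ch)), 1L)
  expect_gte(attr(m, "log_posterior"),
             log_posterior_unnorm(pm, cur, 1, ch$priors))
  # single retained sweep: the MAP is that sample
  ch1 <- run_remc(cur, 1, ladder = fast_ladder(4), n_burn = 100,
                  n_samples = 1, seed = 4)
  expect_equal(par_vector(map_estimate(ch1)),
               unname(replica_trace(ch1)[1, ]))
})

test_that("MAP recovers the truth in the high-count limit", {
  scen <- scenario(sphere_params(R = 10, S = 100, B = 0.01), T = 1e3,
                   N = 200, label = "bright")
  cur <- generate_curve(scen, 1)
  ch <- run_remc(cur, 1, ladder = fast_ladder(10, beta_min = 1e-9),
                 n_burn = 2000, n_samples = 2000, seed = 13)
  m <- map_estimate(ch)
  expect_lt(abs(m$R - 10) / 10, 0.01)
  expect_lt(abs(m$S - 100) / 100, 0.02)
})

test_that("standardized residuals have the Poisson normalization", {
  cur <- sas_curve(q = c(1, 2), y = c(4, 2), T = 1)
  p <- flat_params(2)
  expect_equal(scattering_residuals(p, cur), c((4 - 2) / sqrt(2), 0))
  p1 <- flat_params(1)
  expect_equal(scattering_residuals(p1, sas_curve(1, 4, 1)), 3)
  # moments under the true model: mean 0, variance 1
  set.seed(6)
  scen <- small_scenario()
  truth <- scen$params
  z <- unlist(lapply(1:40, function(s) {
    scattering_residuals(truth, generate_curve(scen, s))
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.1)
  # ties to the chi-squared definition
  cur2 <- small_curve(3)
  expect_equal(sum(scattering_residuals(truth, cur2)^2),
               chi_squared(truth, cur2), tolerance = 1e-10)
})

test_that("posterior envelopes are ordered and tighten with more counts", {
  ch <- run_remc(small_curve(2, T = 1), 1, ladder = fast_ladder(6),
                 n_burn = 800, n_samples = 1500, seed = 31)
  env <- posterior_curve_envelope(ch, n_draws = 300, seed = 1)
  expect_true(all(env$bands[, 1] <= env$bands[, 3]))
  expect_equal(dim(env$draws), c(300L, ch$curve$N))
  # using every sample is a permutation of the full set of curves
  env_all <- posterior_curve_envelope(ch, n_draws = ch$n_samples, seed = 2)
  direct <- intensity(vec_to_params(replica_trace(ch)[7, ], 1L), ch$curve$q)
  expect_true(any(apply(env_all$draws, 1, function(r) isTRUE(all.equal(r, direct)))))
  # lower pseudo-time means fewer counts and a wider envelope
  ch_noisy <- run_remc(small_curve(2, T = 0.1), 1, ladder = fast_ladder(6),
                       n_burn = 800, n_samples = 1500, seed = 31)
  env_noisy <- posterior_curve_envelope(ch_noisy, n_draws = 300, seed = 1)
  width <- mean(env$bands[, 3] - env$bands[, 1])
  width_noisy <- mean(env_noisy$bands[, 3] - env_noisy$bands[, 1])
  expect_gt(width_noisy, width)
  expect_error(posterior_curve_envelope(ch, n_draws = 1e6), "trace length")
})

test_that("credible intervals are calibrated on repeated simulations", {
  scen <- small_scenario(N = 60)
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    ch <- run_remc(generate_curve(scen, s), 1, ladder = fast_ladder(6),
                   n_burn = 500, n_samples = 800, seed = 1000 + s)
    ci <- credible_intervals(ch)["R1", ]
    hits <- hits + (ci["lower"] <= 5 && 5 <= ci["upper"])
  }
  expect_gte(hits, 15L)  # nominal 95%, generous floor for MC error
})
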