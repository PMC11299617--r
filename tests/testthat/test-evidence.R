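# a minimal chain-like object for unit tests of the evidence estimators
fake_chain <- function(E, betas, N = 10L) {
  structure(list(E = E, betas = betas, N = N, n_samples = nrow(E),
                 curve = NULL), class = "remc_chain")
}

test_that("zero cost gives log evidence zero and an unanchored ladder errors", {
  E <- matrix(0, nrow = 50, ncol = 3)
  expect_equal(log_marginal_likelihood(fake_chain(E, c(0, 0.5, 1))), 0)
  expect_equal(log_marginal_likelihood(fake_chain(E, c(0, 0.5, 1)), "ti"), 0)
  expect_error(log_marginal_likelihood(fake_chain(E, c(0.2, 1))), "unanchored")
})

test_that("stepping stone matches the conjugate closed-form evidence", {
  pr <- prior_set(prior_B = gamma_prior(2, 3))
  cur <- flat_curve(N = 30, B = 4, T = 1, seed = 12)
  ch <- run_remc(cur, 0, pr, temperature_ladder(12, 1e-6),
                 n_burn = 2000, n_samples = 6000, seed = 5)
  lz <- log_marginal_likelihood(ch)
  exact <- conjugate_log_evidence(cur$y, cur$T, 2, 3)
  se <- evidence_mc_error(ch, n_boot = 200, seed = 1)$se
  expect_lt(abs(lz - exact), 3 * max(se, 0.01))
})

test_that("a two-rung ladder reduces to prior-average importance sampling", {
  pr <- prior_set(prior_B = gamma_prior(2, 2))
  cur <- flat_curve(N = 5, B = 2, T = 1, seed = 30)
  ch <- run_remc(cur, 0, pr, ladder = c(0, 1), n_burn = 1000,
                 n_samples = 8000, seed = 41)
  lz <- log_marginal_likelihood(ch)
  # independent brute force over iid prior draws
  set.seed(77)
  Bdraws <- rgamma(4e4, 2, scale = 2)
  NE <- vapply(Bdraws, function(b) {
    cur$N * poisson_cost(flat_params(b), cur)
  }, numeric(1))
  m <- max(-NE)
  brute <- m + log(mean(exp(-NE - m)))
  exact <- conjugate_log_evidence(cur$y, cur$T, 2, 2)
  se <- evidence_mc_error(ch, n_boot = 200, seed = 2)$se
  expect_lt(abs(lz - exact), 3 * max(se, 0.02))
  expect_lt(abs(brute - exact), 0.05)  # oracle agrees with the closed form
})

test_that("refining the ladder leaves the evidence unchanged within error", {
  pr <- prior_set(prior_B = gamma_prior(2, 3))
  cur <- flat_curve(N = 30, B = 4, T = 1, seed = 12)
  coarse <- run_remc(cur, 0, pr, temperature_ladder(8, 1e-6),
                     n_burn = 1500, n_samples = 5000, seed = 6)
  fine <- run_remc(cur, 0, pr, temperature_ladder(16, 1e-6),
                   n_burn = 1500, n_samples = 5000, seed = 7)
  d <- abs(log_marginal_likelihood(coarse) - log_marginal_likelihood(fine))
  se <- sqrt(evidence_mc_error(coarse, seed = 3)$se^2 +
             evidence_mc_error(fine, seed = 4)$se^2)
  expect_lt(d, 4 * max(se, 0.01))
})

test_that("model posterior is a shift-invariant softmax", {
  expect_equal(unname(model_posterior(rep(2.5, 4))), rep(0.25, 4))
  expect_equal(unname(model_posterior(c(0, log(9)))), c(0.9, 0.1))
  F <- c(K1 = 3, K2 = 1, K3 = 7)
  expect_equal(model_posterior(F), model_posterior(F + 123.4))
  expect_equal(sum(model_posterior(F)), 1)
  # argmax unaffected by rescaling the model prior by a constant
  lp <- log(c(0.2, 0.5, 0.3))
  expect_equal(which.max(model_posterior(F, lp)),
               which.max(model_posterior(F, lp + 5)))
  expect_error(model_posterior(c(Inf, Inf)), "infinite")
})

test_that("bootstrap SE is zero for constant traces and flags n_boot = 1", {
  E <- matrix(2, nrow = 100, ncol = 3)
  ch <- fake_chain(E, c(0, 0.5, 1))
  expect_equal(evidence_mc_error(ch, n_boot = 50, seed = 1)$se, 0)
  expect_warning(out <- evidence_mc_error(ch, n_boot = 1), "degenerate")
  expect_true(out$degenerate)
  expect_equal(out$se, 0)
  expect_error(evidence_mc_error(fake_chain(E, c(0, 1)), block_len = 200),
               "shorter than")
})

test_that("bootstrap SE shrinks with longer traces", {
  pr <- prior_set(prior_B = gamma_prior(2, 3))
  cur <- flat_curve(N = 30, B = 4, T = 1, seed = 12)
  short <- run_remc(cur, 0, pr, temperature_ladder(8, 1e-6),
                    n_burn = 500, n_samples = 1000, seed = 8)
  long <- run_remc(cur, 0, pr, temperature_ladder(8, 1e-6),
                   n_burn = 500, n_samples = 8000, seed = 8)
  expect_lt(evidence_mc_error(long, n_boot = 100, seed = 5)$se,
            evidence_mc_error(short, n_boot = 100, seed = 5)$se)
})
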