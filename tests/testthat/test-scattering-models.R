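test_that("sphere amplitude has the right limits, values and first zero", {
  expect_equal(form_factor_sq(0), 1.0)
  expect_equal(form_factor_sq(pi), (3 / pi^2)^2, tolerance = 1e-12)
  # the small-x series and the direct formula agree where both are accurate,
  # and the curve is smooth and decreasing near the origin
  x <- seq(0.05, 1, by = 0.001)
  direct <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_equal(form_factor_sq(x), direct, tolerance = 1e-10)
  small <- form_factor_sq(seq(0, 0.5, by = 1e-3))
  expect_true(all(diff(small) < 0))
  z <- sphere_amplitude_first_zero()
  expect_equal(z, 4.4934094579, tolerance = 1e-4)
  expect_lt(form_factor_sq(z), 1e-20)
  expect_error(form_factor_sq(-1), "non-negative")
  expect_true(all(form_factor_sq(seq(0, 50, by = 0.01)) <= 1))
})

test_that("intensity follows the volume-weighted mixture formula", {
  V <- function(R) 4 / 3 * pi * R^3
  # forward limit: Phi(0)^2 = 1 for every component
  p <- sphere_params(R = c(2, 10), S = c(250, 250), B = 0.01)
  q0 <- 1e-6
  expect_equal(intensity(p, q0), 250 * V(10) + 250 * V(2) + 0.01,
               tolerance = 1e-8)
  # single sphere at q R = pi, against hand arithmetic
  p1 <- sphere_params(R = 10, S = 100, B = 0.01)
  expect_equal(intensity(p1, pi / 10), 100 * V(10) * (3 / pi^2)^2 + 0.01,
               tolerance = 1e-10)
  # background floor
  q <- make_qgrid(100)
  expect_true(all(intensity(p, q) >= p$B))
  expect_equal(intensity(flat_params(2.5), q), rep(2.5, 100))
})

test_that("mixture intensity is additive and scale equivariant", {
  set.seed(7)
  q <- make_qgrid(80)
  for (K in 2:4) {
    R <- sort(runif(K, 0.5, 12), decreasing = TRUE)
    S <- runif(K, 0.1, 300)
    B <- runif(1, 0.01, 5)
    p <- sphere_params(R, S, B)
    singles <- vapply(seq_len(K),
                      function(k) intensity(sphere_params(R[k], S[k], B), q),
                      numeric(length(q)))
    expect_equal(intensity(p, q), rowSums(singles) - (K - 1) * B,
                 tolerance = 1e-10)
    cc <- 3.7
    p_scaled <- sphere_params(R, cc * S, cc * B)
    expect_equal(intensity(p_scaled, q), cc * intensity(p, q),
                 tolerance = 1e-10)
  }
})

test_that("single-component intensity decays inside the high-q envelope", {
  p <- sphere_params(R = 8, S = 120, B = 0.5)
  q <- seq(1, 5, length.out = 200)   # q R from 8 to 40
  x <- q * p$R
  envelope <- p$S * (4 / 3 * pi * p$R^3) * 9 * (1 + x)^2 / x^6
  expect_true(all(intensity(p, q) - p$B <= envelope + 1e-12))
})

test_that("sphere parameter container validates and orders components", {
  p <- sphere_params(R = c(2, 10, 5), S = c(1, 2, 3), B = 0.1)
  expect_equal(p$R, c(10, 5, 2))
  expect_equal(p$S, c(2, 3, 1))  # scales follow their radii
  expect_equal(p$K, 3L)
  expect_error(sphere_params(R = c(1, -2), S = c(1, 1), B = 1), "positive")
  expect_error(sphere_params(R = 1, S = c(1, 2), B = 1), "equal")
  expect_error(sphere_params(R = 1, S = 1, B = 0), "positive")
  expect_error(flat_params(-1), "positive")
})

test_that("q grids are evenly spaced with inclusive endpoints", {
  q <- make_qgrid()
  expect_length(q, 400L)
  expect_equal(q[1], 0.1)
  expect_equal(q[400], 3.0)
  expect_equal(unique(round(diff(q), 12)), round(2.9 / 399, 12))
  expect_equal(make_qgrid(2), c(0.1, 3.0))
  expect_error(make_qgrid(1), "at least 2")
  expect_error(intensity(flat_params(1), c(2, 1, 3)), "increasing")
})

test_that("model registry exposes built-ins and accepts new entries", {
  expect_true(all(c("sphere_mixture", "flat_background") %in% list_sas_models()))
  m <- get_sas_model("sphere_mixture")
  expect_equal(m$n_params(3), 7L)
  p <- sphere_params(5, 10, 0.1)
  expect_equal(m$intensity(p, make_qgrid(10)), intensity(p, make_qgrid(10)))
  register_sas_model("test_dummy", function(params, q) rep(1, length(q)),
                     function(K) 0L)
  expect_true("test_dummy" %in% list_sas_models())
  expect_error(get_sas_model("no_such_model"), "unknown model")
})
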