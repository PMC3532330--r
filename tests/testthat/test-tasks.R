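test_that("measurements are reproducible, seeded, and carry calibrated noise", {
  g <- time_grid(1, n = 1000)
  y <- rep(2, 1000)
  clean <- add_noise(y, g, 0)
  expect_identical(clean$y_meas, y)
  a <- add_noise(y, g, 0.05, seed = 99)
  b <- add_noise(y, g, 0.05, seed = 99)
  expect_identical(a$y_meas, b$y_meas)
  expect_false(identical(a$y_meas, add_noise(y, g, 0.05, seed = 100)$y_meas))
  # mean absolute relative deviation of multiplicative N(0, level) noise
  # is level * sqrt(2/pi) (half-normal mean)
  mad_rel <- mean(abs(a$y_meas / y - 1))
  expect_equal(mad_rel, 0.05 * sqrt(2 / pi), tolerance = 0.1)
  expect_error(add_noise(y, g, 0.05), "seed")
  expect_error(add_noise(y[1:5], g, 0), "length")
})

test_that("the least-squares cost is an exact trapezoidal quadrature", {
  s <- bd_setup()
  # self-measurement at the generating parameters has (numerically) zero cost
  y_self <- as.numeric(solve_reduced(s$rmodel, s$ref_theta, s$grid)$y[1, ])
  m_self <- add_noise(y_self, s$grid, 0)
  expect_lt(cost(s$rmodel, s$ref_theta, m_self),
            1e-16 * sum(s$grid$weights * y_self^2))
  # constant-1 prediction against a zero measurement integrates to T
  m_zero <- add_noise(rep(0, length(s$grid$times)), s$grid, 0)
  rm1 <- structure(list(
    Ar = list(matrix(0, 1, 1)), coefs = list(function(th) 1), labels = "c",
    Cr = matrix(1, 1, 1), output_labels = "const", P0r = 1, V = NULL,
    domain = NULL, r = 1L, Q = 1L), class = "reduced_model")
  expect_equal(cost(rm1, list(), m_zero), s$grid$T)
  # brute-force quadrature oracle on a random residual
  set.seed(17)
  y_meas <- y_self + stats::rnorm(length(y_self), sd = 0.3)
  m <- add_noise(y_meas, s$grid, 0)
  direct <- sum(s$grid$weights * (y_meas - y_self)^2)
  expect_equal(cost(s$rmodel, s$ref_theta, m), direct, tolerance = 1e-10)
})

test_that("estimation recovers generating parameters from noiseless data", {
  s <- bd_setup()
  y_hat <- as.numeric(solve_reduced(s$rmodel, s$ref_theta, s$grid)$y[1, ])
  m <- add_noise(y_hat, s$grid, 0, theta_ref = s$ref_theta)
  res <- estimate(s$rmodel, m, lower = c(k = 4), upper = c(k = 16),
                  fixed = s$model$params["gamma"])
  expect_equal(res$convergence, 0L)
  expect_lt(abs(res$theta_est$k - 8) / 8, 5e-4)
  expect_gt(res$evaluations, 1L)
  expect_lte(res$J_est, res$J_ref + 1e-12)
})

test_that("cost landscapes evaluate every node and dip near the truth", {
  s <- bd_setup()
  m <- add_noise(s$y_ref, s$grid, 0, theta_ref = s$ref_theta)
  df <- cost_landscape(s$rmodel, m, values = list(k = seq(4, 16, length.out = 13)),
                       fixed = s$model$params["gamma"])
  expect_equal(nrow(df), 13L)
  expect_true(all(df$J >= 0))
  expect_true(all(is.finite(df$J)))
  expect_equal(df$k[which.min(df$J)], 8, tolerance = 0.1)
  expect_error(cost_landscape(s$rmodel, m, values = list(k = c(1, 8))),
               "admissible")
})

test_that("sensitivity sweeps are deterministic, bounded, and warn on extrapolation", {
  s <- bd_setup()
  vals <- seq(5, 15, length.out = 25)
  a <- sensitivity_sweep(s$rmodel, "k", vals, t_eval = 4, s$grid,
                         fixed = s$model$params["gamma"], output = 2L)
  b <- sensitivity_sweep(s$rmodel, "k", vals, t_eval = 4, s$grid,
                         fixed = s$model$params["gamma"], output = 2L)
  expect_identical(a, b)
  expect_true(all(a$prob >= -1e-8 & a$prob <= 1 + 1e-6))
  # more births shift mass above the region threshold monotonically
  expect_true(all(diff(a$prob) > 0))
  expect_warning(
    sensitivity_sweep(s$rmodel, "k", c(2, 8), t_eval = 4, s$grid,
                      fixed = s$model$params["gamma"], output = 2L),
    "extrapolates")
  expect_error(
    sensitivity_sweep(s$rmodel, "k", vals, t_eval = 99, s$grid,
                      fixed = s$model$params["gamma"]),
    "t_eval")
})
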