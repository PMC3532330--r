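test_that("the switch fixture matches its rate table", {
  sw <- build_switch(bound = 30L)
  expect_equal(sw$operator$Q, 5L)
  expect_equal(sw$params,
               list(k1 = 4, V1 = 75, M1 = 25, u1 = 0.01,
                    V2 = 75, M2 = 25, u2 = 0.01))
  # production of X1 at the Hill midpoint x2 = M1 = 25:
  # u1 * (k1 + V1/2) = 0.01 * 41.5
  prod_x1 <- function(x, th) {
    terms <- sw$network$propensities[c(1, 2)]
    sum(vapply(terms, function(tm)
      tm$coef(th) * evaluate_propensity(tm, x), 0))
  }
  expect_equal(prod_x1(c(0, 25), sw$params), 0.01 * (4 + 37.5))
  # degradation of X1 vanishes at x1 = 0
  deg <- sw$network$propensities[[3]]
  expect_equal(deg$coef(sw$params) * evaluate_propensity(deg, c(0, 10)), 0)
  expect_equal(names(sw$varied), c("u1", "u2"))
  expect_equal(sw$varied$u1, c(0.005, 0.02))
  expect_equal(sw$T_final, 1e7)
})

test_that("the oscillator fixture matches its rate table", {
  osc <- build_oscillator(s = 10, bound = 40L)
  expect_equal(osc$operator$Q, 5L)
  th <- osc$params
  # production of X1 at x2 = 0: k1 s^2 / (k2 s) = 15 * 100 / 2
  t1 <- osc$network$propensities[[1]]
  expect_equal(t1$coef(th) * evaluate_propensity(t1, c(0, 0)), 750)
  # production of X2 at x2 = 0: only the basal term k4 * s = 100 survives
  t3 <- osc$network$propensities[[3]]
  t4 <- osc$network$propensities[[4]]
  expect_equal(t3$coef(th) * evaluate_propensity(t3, c(5, 0)) +
                 t4$coef(th) * evaluate_propensity(t4, c(5, 0)), 100)
  expect_equal(osc$varied$k4, c(10, 100))
  expect_equal(osc$T_final, 6)
})

test_that("separated operators equal direct assembly at nominal parameters (full lattices)", {
  sw <- build_switch()                      # {0..150}^2, d = 22801
  expect_equal(sw$ss$d, 22801L)
  diff_sw <- max(abs(assemble_operator(sw$operator, sw$params) -
                       direct_operator(sw)))
  expect_lt(diff_sw, 1e-12)

  osc <- build_oscillator()                 # {0..300}^2, d = 90601
  expect_equal(osc$ss$d, 90601L)
  diff_osc <- max(abs(assemble_operator(osc$operator, osc$params) -
                        direct_operator(osc)))
  expect_lt(diff_osc, 1e-12)
})

test_that("fixture propensities are nonnegative over their truncation domains", {
  for (model in list(build_switch(bound = 60L), build_oscillator(s = 3))) {
    for (tm in model$network$propensities) {
      vals <- evaluate_propensity(tm, model$ss$states)
      expect_true(all(vals >= 0))
      expect_true(tm$coef(model$params) >= 0)
    }
  }
})

test_that("the birth-death oracle model has the documented closed forms", {
  bd <- build_birth_death(k = 10, gamma = 2, bound = 30L)
  expect_equal(bd$poisson_lambda(Inf), 5)   # stationary mean k/gamma
  # pure birth: mean k*t
  pb <- build_birth_death(k = 3, gamma = 0, bound = 200L)
  expect_equal(pb$poisson_lambda(0.5), 1.5)
  g <- time_grid(0.5, n = 6)
  tr <- solve_full(pb$operator, pb$params, pb$P0, g)
  y <- observe(tr, pb$outputs$Ex)
  expect_equal(as.numeric(y), 3 * g$times, tolerance = 1e-6)
  # no birth: the empty state is absorbing
  dead <- build_birth_death(k = 0, gamma = 1, bound = 10L)
  trd <- solve_full(dead$operator, dead$params, dead$P0, time_grid(2, n = 5))
  expect_equal(trd$P[1, ], rep(1, 5), tolerance = 1e-10)
  expect_error(build_birth_death(k = -1), "nonnegative")
})

test_that("scaled-down oscillator variants rescale the box, start and threshold", {
  osc3 <- build_oscillator(s = 3)
  expect_equal(osc3$ss$upper, c(90L, 90L), ignore_attr = TRUE)
  expect_equal(osc3$P0$support_size, 16L^2)        # uniform on {0..15}^2
  expect_match(osc3$outputs$Pburst$labels, "x2 > 30")
})
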