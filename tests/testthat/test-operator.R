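test_that("hand-assembled two-state components match, including boundary leak", {
  ss <- state_space(0L, 1L)
  birth <- assemble_component(ss, 1L, function(s) rep(1, nrow(s)))
  expect_equal(as.matrix(birth), rbind(c(-1, 0), c(1, -1)), ignore_attr = TRUE)
  # column 2's sum is -1: the birth out of state 1 leaves the box (sink)
  expect_equal(Matrix::colSums(birth), c(0, -1), ignore_attr = TRUE)
  death <- assemble_component(ss, -1L, function(s) s[, 1])
  expect_equal(as.matrix(death), rbind(c(0, 1), c(0, -1)), ignore_attr = TRUE)
  zero <- assemble_component(ss, 1L, function(s) rep(0, nrow(s)))
  expect_equal(Matrix::nnzero(zero), 0)
})

test_that("assembled operators are proper sink-type FSP generators", {
  set.seed(7)
  sw <- build_switch(bound = 25L)
  for (trial in 1:5) {
    theta <- model_params(sw, list(u1 = stats::runif(1, 0.005, 0.02),
                                   u2 = stats::runif(1, 0.005, 0.02)))
    A <- assemble_operator(sw$operator, theta)
    M <- as.matrix(A)
    expect_true(all(M[row(M) != col(M)] >= 0))
    expect_true(all(diag(M) <= 0))
    cs <- Matrix::colSums(A)
    expect_true(all(cs <= 1e-12))
    # interior states (all reaction targets inside the box) conserve mass
    interior <- sw$ss$states[, 1] > 0 & sw$ss$states[, 1] < 25 &
      sw$ss$states[, 2] > 0 & sw$ss$states[, 2] < 25
    expect_true(all(abs(cs[interior]) < 1e-12))
  }
})

test_that("the separable decomposition reproduces direct assembly for random parameters", {
  set.seed(11)
  sw <- build_switch(bound = 40L)
  for (trial in 1:4) {
    theta <- model_params(sw, list(u1 = stats::runif(1, 0.005, 0.02),
                                   u2 = stats::runif(1, 0.005, 0.02)))
    A_sep <- assemble_operator(sw$operator, theta)
    A_dir <- direct_operator(sw, theta)
    expect_lt(max(abs(A_sep - A_dir)), 1e-12)
  }
})

test_that("operator evaluation degenerates correctly and guards its domain", {
  ss <- state_space(0L, 3L)
  net <- reaction_network("x1",
    list(list(reactant = 0L, product = 1L)),
    list(mass_action_term(1L, "k", 0L)))
  po <- parametric_operator(net, ss, domain = list(k = c(0, 10)))
  expect_equal(as.matrix(assemble_operator(po, list(k = 1))),
               as.matrix(po$components[[1]]), ignore_attr = TRUE)
  expect_equal(Matrix::nnzero(assemble_operator(po, list(k = 0))), 0)
  expect_error(assemble_operator(po, list(k = 50)), "outside admissible range")
  expect_error(assemble_component(ss, c(1L, 1L), function(s) rep(1, nrow(s))),
               "length")
})

test_that("expectation rows hold state coordinates in enumeration order", {
  ss <- state_space(c(0L, 0L), c(1L, 1L))
  om <- output_expectation(ss, "x1")
  expect_equal(as.numeric(om$C), c(0, 1, 0, 1))
  om2 <- output_expectation(ss, "x2")
  expect_equal(as.numeric(om2$C), c(0, 0, 1, 1))
  expect_error(output_expectation(ss, "x9"), "unknown species")
})

test_that("region rows are indicators with the right cardinality", {
  ss <- state_space(c(0L, 0L), c(300L, 300L))
  om <- output_region(ss, function(s) s[, 2] > 100L, "Prob(x2 > 100)")
  expect_equal(Matrix::nnzero(om$C), 301L * 200L)
  expect_true(all(om$C@x == 1))
  empty <- output_region(ss, function(s) rep(FALSE, nrow(s)))
  expect_equal(Matrix::nnzero(empty$C), 0)
})

test_that("uniform initial distributions normalize by the true support count", {
  ss_osc <- state_space(c(0L, 0L), c(300L, 300L))
  p0 <- initial_uniform(ss_osc, function(s) s[, 1] <= 50L & s[, 2] <= 50L)
  expect_equal(p0$support_size, 2601L)
  expect_equal(max(p0$P0), 1 / 51^2)
  expect_equal(sum(p0$P0), 1, tolerance = 1e-12)

  ss_sw <- state_space(c(0L, 0L), c(150L, 150L))
  tri <- initial_uniform(ss_sw, function(s) rowSums(s) <= 20L)
  expect_equal(tri$support_size, 231L)          # sum_{s=0}^{20} (s+1)
  expect_equal(max(tri$P0), 1 / 231)

  all_states <- initial_uniform(ss_osc, function(s) rep(TRUE, nrow(s)))
  expect_equal(unique(all_states$P0), 1 / ss_osc$d)
  expect_error(initial_uniform(ss_sw, function(s) rep(FALSE, nrow(s))),
               "no state")
})

test_that("the switch initial-condition variants have supports 231 and 210", {
  expect_equal(build_switch(bound = 30L)$P0$support_size, 231L)
  expect_equal(build_switch(bound = 30L, init_variant = "210")$P0$support_size, 210L)
})
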