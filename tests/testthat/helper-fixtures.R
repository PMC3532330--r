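# Shared fixtures. The heavy ones (scaled-down switch and oscillator
# studies) are built lazily and memoized so several test files can use
# them without re-simulating the training trajectories.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# random sink-type FSP-like operator on n states: nonnegative
# off-diagonals, diagonal dominated columns (column sums <= 0)
random_sink_operator <- function(n, density = 0.4) {
  M <- matrix(stats::runif(n * n), n, n) * (matrix(stats::runif(n * n), n, n) < density)
  diag(M) <- 0
  diag(M) <- -colSums(M) - stats::runif(n, 0, 0.5)
  Matrix::Matrix(M, sparse = TRUE)
}

random_probability <- function(n) {
  p <- stats::runif(n)
  p / sum(p)
}

# dense matrix-exponential propagation: the independent oracle for the
# ODE solvers on small instances
expm_propagate <- function(A, P0, times) {
  A <- as.matrix(A)
  vapply(times, function(t)
    as.numeric(Matrix::expm(t * A) %*% P0), numeric(length(P0)))
}

# birth-death task setup: greedy basis over the birth rate (d = 41),
# stacked expectation + region outputs; cheap enough for fast task tests
bd_setup <- function() memo("bd_tasks", function() {
  model <- build_birth_death(k = 8, gamma = 1, bound = 40L)
  model$operator$domain <- list(k = c(4, 16))
  grid <- time_grid(4, n = 41)
  theta_train <- make_training_set(list(k = c(4, 16)), 5, spacing = "linear")
  rb <- pod_greedy(operator = model$operator, P0 = model$P0, grid = grid,
                   theta_train = theta_train, fixed = model$params,
                   V_init = model$P0$P0, eps_tol = 1e-12)
  om <- output_stack(model$outputs$Ex,
                     output_region(model$ss, function(s) s[, 1] > 5L,
                                   "Prob(x1 > 5)"))
  rmodel <- reduce_model(model$operator, om, model$P0, rb)
  ref_theta <- model_params(model)
  y_ref <- observe(solve_full(model$operator, ref_theta, model$P0, grid),
                   model$outputs$Ex)[1, ]
  list(model = model, grid = grid, rmodel = rmodel, y_ref = y_ref,
       ref_theta = ref_theta)
})

# scaled-down switch study: {0..80}^2 lattice, T = 1e6, 3x3
# log-equidistant training grid, eps_tol = 1e-8; log-spaced snapshots
# (the transient lives decades before T)
scaled_switch <- function() memo("scaled_switch", function() {
  model <- build_switch(bound = 80L, T_final = 1e6)
  grid <- time_grid(1e6, n = 80, spacing = "log", t1 = 1)
  theta_train <- make_training_set(model$varied, 3, spacing = "log")
  trajectories <- lapply(seq_len(nrow(theta_train)), function(i) {
    th <- model_params(model, as.list(theta_train[i, ]))
    solve_full(model$operator, th, model$P0, grid)
  })
  basis <- pod_greedy(trajectories = trajectories, V_init = model$P0$P0,
                      eps_tol = 1e-8)
  rmodel <- reduce_model(model$operator, model$outputs$Ex1, model$P0, basis)
  list(model = model, grid = grid, theta_train = theta_train,
       trajectories = trajectories, basis = basis, rmodel = rmodel)
})

# estimation study on the full switch lattice ({0..150}^2, T = 1e7):
# reduced basis trained along the u2 = 0.01 restriction (5 log points
# in u1, eps_tol = 1e-10); measurement = full-model E[x1] at
# (u1, u2) = (0.01, 0.01) sampled on a uniform 1000-point grid
switch_estimation <- function() memo("switch_estimation", function() {
  model <- build_switch()
  grid_train <- time_grid(model$T_final, n = 80, spacing = "log", t1 = 1)
  u1_train <- as.numeric(make_training_set(list(u1 = c(0.005, 0.02)), 5, "log"))
  trajectories <- lapply(u1_train, function(u1)
    solve_full(model$operator,
               model_params(model, list(u1 = u1, u2 = 0.01)),
               model$P0, grid_train))
  basis <- pod_greedy(trajectories = trajectories, V_init = model$P0$P0,
                      eps_tol = 1e-10)
  rmodel <- reduce_model(model$operator, model$outputs$Ex1, model$P0, basis)
  theta_ref <- model_params(model, list(u1 = 0.01, u2 = 0.01))
  grid_meas <- time_grid(model$T_final, n = 1000)
  y_ref <- observe(solve_full(model$operator, theta_ref, model$P0, grid_meas),
                   model$outputs$Ex1)[1, ]
  list(model = model, rmodel = rmodel, basis = basis,
       grid_meas = grid_meas, y_ref = y_ref, theta_ref = theta_ref,
       fixed = model$params[setdiff(names(model$params), "u1")])
})

# scaled-down oscillator study at system size s = 3 ({0..90}^2),
# 9 log-equidistant training values of k4 on [10, 100], eps_tol 1e-11
scaled_oscillator <- function() memo("scaled_oscillator", function() {
  model <- build_oscillator(s = 3)
  grid <- time_grid(6, n = 80, spacing = "log", t1 = 1e-3)
  theta_train <- make_training_set(model$varied, 9, spacing = "log")
  trajectories <- lapply(seq_len(nrow(theta_train)), function(i) {
    th <- model_params(model, as.list(theta_train[i, ]))
    solve_full(model$operator, th, model$P0, grid)
  })
  basis <- pod_greedy(trajectories = trajectories, V_init = model$P0$P0,
                      eps_tol = 1e-11)
  rmodel <- reduce_model(model$operator, model$outputs$Pburst, model$P0, basis)
  list(model = model, grid = grid, theta_train = theta_train,
       trajectories = trajectories, basis = basis, rmodel = rmodel)
})
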