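test_that("the dominant POD mode solves the small eigenproblems exactly", {
  # constant trajectory: the mode is the (normalized) state itself
  p <- c(3, 0, 4)
  X <- cbind(p, p, p)
  expect_equal(pod_first_mode(X, weights = c(1, 1, 1)), p / 5)
  # two orthogonal snapshots: the heavier one wins
  X2 <- cbind(10 * c(1, 0), 0.1 * c(0, 1))
  expect_equal(pod_first_mode(X2, weights = c(1, 1)), c(1, 0))
  expect_error(pod_first_mode(matrix(0, 3, 2), weights = c(1, 1)), "all-zero")
})

test_that("method of snapshots agrees with the dense correlation eigenproblem", {
  set.seed(19)
  for (trial in 1:5) {
    X <- matrix(stats::rnorm(5 * 7), 5, 7)
    w <- stats::runif(7, 0.1, 2)
    v <- pod_first_mode(X, weights = w)
    # dense oracle: eigenvector of C = sum_k w_k P_k P_k'
    C <- X %*% (w * t(X))
    ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
    if (ev[which.max(abs(ev))] < 0) ev <- -ev
    expect_equal(v, ev, tolerance = 1e-10)
  }
})

test_that("projection errors match brute-force computation and edge cases", {
  set.seed(23)
  X <- matrix(stats::rnorm(6 * 9), 6, 9)
  w <- rep(0.5, 9)
  V <- qr.Q(qr(matrix(stats::rnorm(6 * 2), 6, 2)))
  direct <- sum(w * vapply(1:9, function(k) {
    r <- X[, k] - V %*% crossprod(V, X[, k])
    sum(r^2)
  }, 0))
  expect_equal(projection_error(X, V, weights = w), direct, tolerance = 1e-12)
  # a basis spanning the snapshots has zero projection error
  Vfull <- qr.Q(qr(X[, 1:6]))
  expect_lt(projection_error(X, Vfull, weights = w), 1e-20 * sum(X^2))
  # the empty basis leaves the full weighted energy
  expect_equal(projection_error(X, matrix(0, 6, 0), weights = w),
               sum(w * colSums(X^2)))
  expect_error(projection_error(X, X[, 1:2], weights = w), "not orthonormal")
})

test_that("POD-Greedy recovers an exact basis for low-rank training data", {
  set.seed(31)
  d <- 40; k <- 3
  U <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  grid <- time_grid(1, n = 12)
  fake_traj <- function(i) {
    coef <- matrix(stats::rnorm(k * 12), k, 12)
    structure(list(grid = grid, P = U %*% coef, theta = list(id = i),
                   method = "synthetic"), class = "full_trajectory")
  }
  trajs <- lapply(1:6, fake_traj)
  v0 <- U %*% stats::rnorm(k); v0 <- v0 / sqrt(sum(v0^2))
  rb <- pod_greedy(trajectories = trajs, V_init = v0, eps_tol = 1e-20)
  expect_equal(rb$report$status, "converged")
  expect_lte(ncol(rb$V), k + 1)          # at most k new modes over V_init
  expect_lt(rb$report$eps[length(rb$report$eps)], 1e-20)
  expect_true(all(diff(rb$report$eps) <= 1e-25))
  # orthonormality is maintained after every extension
  expect_lt(max(abs(crossprod(rb$V) - diag(ncol(rb$V)))), 1e-10)
})

test_that("greedy training errors decrease monotonically on generic data", {
  set.seed(37)
  grid <- time_grid(1, n = 10)
  trajs <- lapply(1:4, function(i)
    structure(list(grid = grid, P = matrix(stats::rnorm(30 * 10), 30, 10),
                   theta = list(id = i), method = "synthetic"),
              class = "full_trajectory"))
  v0 <- rep(1, 30) / sqrt(30)
  rb <- pod_greedy(trajectories = trajs, V_init = v0, eps_tol = 1e-12,
                   max_size = 15)
  expect_true(all(diff(rb$report$eps) <= 1e-12))
  expect_equal(rb$report$basis_sizes, seq_len(length(rb$report$eps)))
})

test_that("Galerkin projection reduces components consistently", {
  set.seed(41)
  bd <- build_birth_death(k = 4, gamma = 0.8, bound = 30L)
  d <- bd$ss$d
  # identity basis: reduction is exact
  rm_id <- reduce_model(bd$operator, bd$outputs$Ex, bd$P0, diag(d))
  for (q in 1:2)
    expect_equal(rm_id$Ar[[q]], as.matrix(bd$operator$components[[q]]),
                 ignore_attr = TRUE)
  expect_equal(rm_id$P0r, bd$P0$P0)
  # r = 3: every reduced piece is 3-dimensional
  V <- qr.Q(qr(matrix(stats::rnorm(d * 3), d, 3)))
  rm3 <- reduce_model(bd$operator, bd$outputs$Ex, bd$P0, V)
  expect_true(all(vapply(rm3$Ar, function(m) all(dim(m) == c(3, 3)), TRUE)))
  expect_equal(dim(rm3$Cr), c(1L, 3L))
  # triple products match dense computation
  for (q in 1:2)
    expect_equal(rm3$Ar[[q]],
                 t(V) %*% as.matrix(bd$operator$components[[q]]) %*% V,
                 tolerance = 1e-12)
  expect_error(reduce_model(bd$operator, bd$outputs$Ex, bd$P0,
                            matrix(stats::rnorm(d * 2), d, 2)),
               "not orthonormal")
})

test_that("identity-basis reduced solves reproduce the full model", {
  bd <- build_birth_death(k = 6, gamma = 1, bound = 45L)
  g <- time_grid(3, n = 13)
  full <- solve_full(bd$operator, bd$params, bd$P0, g)
  y_full <- observe(full, bd$outputs$Ex)
  rm_id <- reduce_model(bd$operator, bd$outputs$Ex, bd$P0, diag(bd$ss$d))
  red <- solve_reduced(rm_id, bd$params, g)
  expect_equal(as.numeric(red$y), as.numeric(y_full), tolerance = 1e-6)
  # reconstruction with the identity basis returns the states themselves
  expect_equal(reconstruct(diag(bd$ss$d), red), red$Pr)
})

test_that("a zero reduced operator freezes the reduced state", {
  rm <- structure(list(
    Ar = list(matrix(0, 2, 2)), coefs = list(function(th) th$k),
    labels = "k", Cr = matrix(1, 1, 2), output_labels = "sum",
    P0r = c(0.3, 0.7), V = NULL, domain = NULL, r = 2L, Q = 1L),
    class = "reduced_model")
  tr <- solve_reduced(rm, list(k = 0), time_grid(2, n = 5))
  expect_equal(tr$Pr, matrix(c(0.3, 0.7), 2, 5))
  expect_equal(as.numeric(tr$y), rep(1, 5))
})

test_that("reduced solvers agree with each other", {
  set.seed(43)
  bd <- build_birth_death(k = 5, gamma = 1, bound = 40L)
  V <- qr.Q(qr(cbind(bd$P0$P0, matrix(stats::rnorm(41 * 4), 41, 4))))
  rm <- reduce_model(bd$operator, bd$outputs$Ex, bd$P0, V)
  g <- time_grid(3, n = 11)
  a <- solve_reduced(rm, bd$params, g, method = "expm")
  b <- solve_reduced(rm, bd$params, g, method = "lsoda")
  expect_equal(a$Pr, b$Pr, tolerance = 1e-7)
})
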