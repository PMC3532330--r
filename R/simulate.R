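#' Output time grid with trapezoidal quadrature weights
#'
#' @param T final time (> 0).
#' @param n number of grid points including 0 and T (default 100).
#' @param spacing \code{"linear"} or \code{"log"}; log spacing starts at
#'   \code{t1} (then 0 is prepended) and is useful for long stiff
#'   horizons where the transient lives at early times.
#' @param t1 first positive time for log spacing (default \code{T * 1e-6}).
#' @return Object of class \code{time_grid}: \code{times} (strictly
#'   increasing, \code{times[1] == 0}), \code{T}, and trapezoidal
#'   \code{weights} summing to \code{T}.
#' @export
time_grid <- function(T, n = 100L, spacing = c("linear", "log"),
                      t1 = T * 1e-6) {
  spacing <- match.arg(spacing)
  if (T <= 0) stop("final time must be positive")
  if (n < 2L) stop("grid needs at least 2 points")
  times <- switch(spacing,
    linear = seq(0, T, length.out = n),
    log = c(0, exp(seq(log(t1), log(T), length.out = n - 1L))))
  as_time_grid(times)
}

#' Turn an arbitrary increasing time vector into a grid
#' @param times strictly increasing, starting at 0.
#' @export
as_time_grid <- function(times) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("grid times must be strictly increasing")
  K <- length(times)
  h <- diff(times)
  w <- numeric(K)
  w[1] <- h[1] / 2
  w[K] <- h[K - 1] / 2
  if (K > 2L) w[2:(K - 1)] <- (h[-1] + h[-(K - 1)]) / 2
  structure(list(times = times, T = times[K], weights = w),
            class = "time_grid")
}

#' Integrate the full FSP system on a time grid
#'
#' Solves the linear master-equation ODE \eqn{dP/dt = A(\theta) P},
#' \eqn{P(0) = P_0}, and records state snapshots at the grid times.
#' The default integrator is the adaptive stiff multistep method of
#' \code{deSolve::lsodes} with the operator itself supplied as analytic
#' sparse Jacobian; the \code{"expm"} method instead steps between
#' output times with a Krylov action-of-exponential ([krylov_expv()]),
#' which is preferable on very long stiff horizons.
#'
#' @param operator a [parametric_operator()] (give \code{theta}) or an
#'   already assembled sparse matrix (leave \code{theta} NULL).
#' @param theta named parameter vector for a parametric operator.
#' @param P0 initial probability vector (or an \code{initial_distribution}).
#' @param grid a [time_grid()].
#' @param method \code{"lsodes"} (default) or \code{"expm"}.
#' @param rtol,atol solver tolerances (lsodes) — defaults 1e-8 / 1e-12.
#' @param expv_tol local tolerance of the Krylov stepper.
#' @param krylov_dim Krylov subspace dimension for \code{"expm"}.
#' @return Object of class \code{full_trajectory}: \code{grid},
#'   \code{P} (a \code{d x K} matrix of snapshots, one column per grid
#'   time), \code{theta}, \code{method}. Snapshots are the raw solver
#'   states; tiny negative entries are only clipped in reported outputs.
#' @export
solve_full <- function(operator, theta = NULL, P0, grid,
                       method = c("lsodes", "expm"),
                       rtol = 1e-8, atol = 1e-12,
                       expv_tol = 1e-8, krylov_dim = 30L) {
  method <- match.arg(method)
  A <- if (inherits(operator, "parametric_operator")) {
    if (is.null(theta)) stop("theta required for a parametric operator")
    assemble_operator(operator, theta)
  } else {
    # normalize to general CSC storage (diagonal/triangular/dense inputs)
    methods::as(methods::as(Matrix::Matrix(operator, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  }
  if (inherits(P0, "initial_distribution")) P0 <- P0$P0
  P0 <- as.numeric(P0)
  if (length(P0) != nrow(A)) stop("initial condition length does not match operator")
  if (abs(sum(P0) - 1) > 1e-8)
    warning("initial condition mass deviates from 1 by ", signif(abs(sum(P0) - 1), 3))
  times <- grid$times
  d <- length(P0)

  P <- if (method == "lsodes") {
    cols <- lapply(seq_len(d), function(j) {
      if (A@p[j + 1L] == A@p[j]) integer() else
        A@i[(A@p[j] + 1L):A@p[j + 1L]] + 1L
    })
    inz <- rbind(cbind(unlist(cols), rep(seq_len(d), lengths(cols))),
                 cbind(seq_len(d), seq_len(d)))   # keep full diagonal in pattern
    inz <- inz[!duplicated(inz), , drop = FALSE]
    inz <- inz[order(inz[, 2], inz[, 1]), , drop = FALSE]
    colvec <- function(t, y, j, parms) {
      # direct CSC column extraction; A[, j] dispatch is too slow here
      z <- numeric(d)
      if (A@p[j + 1L] > A@p[j]) {
        idx <- (A@p[j] + 1L):A@p[j + 1L]
        z[A@i[idx] + 1L] <- A@x[idx]
      }
      z
    }
    sol <- deSolve::lsodes(
      y = P0, times = times,
      func = function(t, y, parms) list(as.numeric(A %*% y)),
      parms = NULL, rtol = rtol, atol = atol,
      jacvec = colvec, sparsetype = "sparseusr", inz = inz,
      lrw = as.double(32 * nrow(inz) + 32 * d + 1000),  # room for LU fill-in
      maxsteps = 100000)
    if (nrow(sol) != length(times))
      stop("integrator failed at t = ", sol[nrow(sol), 1],
           " (stiffness or step underflow; see diagnostics(sol))")
    t(unname(sol[, -1, drop = FALSE]))
  } else {
    out <- matrix(0, d, length(times))
    out[, 1] <- P0
    w <- P0
    for (k in seq_along(times)[-1]) {
      w <- krylov_expv(A, w, times[k] - times[k - 1],
                       m = krylov_dim, tol = expv_tol)
      out[, k] <- w
    }
    out
  }
  structure(list(grid = grid, P = P, theta = theta, method = method,
                 rtol = rtol, atol = atol),
            class = "full_trajectory")
}

#' @exportS3Method base::print
print.full_trajectory <- function(x, ...) {
  cat("FSP trajectory:", nrow(x$P), "states x", ncol(x$P), "times, T =",
      x$grid$T, "(", x$method, ")\n")
  cat("  final mass:", sum(x$P[, ncol(x$P)]), "\n")
  invisible(x)
}

#' Apply an output map to a trajectory
#'
#' Returns the output time series \eqn{y(t_k) = C P(t_k)}. Tiny negative
#' snapshot entries arising from floating point are clipped to 0 here,
#' in the reported outputs only.
#'
#' @param trajectory a \code{full_trajectory} (or any list with fields
#'   \code{P} and \code{grid}).
#' @param output_map an [output_expectation()] / [output_region()] map,
#'   or a bare matrix with d columns.
#' @param clip clip negative probabilities before observing (default TRUE).
#' @return numeric matrix, one row per output, one column per grid time,
#'   with output labels as rownames.
#' @export
observe <- function(trajectory, output_map, clip = TRUE) {
  C <- if (inherits(output_map, "output_map")) output_map$C else output_map
  if (ncol(C) != nrow(trajectory$P)) stop("output map dimension mismatch")
  P <- trajectory$P
  if (clip) P <- pmax(P, 0)
  y <- as.matrix(C %*% P)
  rownames(y) <- if (inherits(output_map, "output_map")) output_map$labels
  y
}

#' Total probability mass over time
#' @param trajectory a \code{full_trajectory}.
#' @return numeric vector of \code{sum(P(t_k))}; non-increasing for a
#'   sink-type FSP operator up to solver tolerance.
#' @export
mass_trace <- function(trajectory) colSums(trajectory$P)
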