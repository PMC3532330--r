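# Offline/online model order reduction: proper orthogonal decomposition
# by the method of snapshots, the POD-Greedy basis loop, and the reduced
# (r-dimensional) parametric model.

snapshot_matrix <- function(trajectory) {
  if (inherits(trajectory, "full_trajectory")) trajectory$P
  else as.matrix(trajectory)
}

snapshot_weights <- function(trajectory, weights = NULL) {
  if (!is.null(weights)) return(weights)
  if (inherits(trajectory, "full_trajectory")) trajectory$grid$weights
  else stop("weights required when snapshots are a bare matrix")
}

#' Dominant POD mode of a trajectory
#'
#' Returns the unit vector minimizing the time-weighted mean squared
#' projection error of the snapshots — the eigenvector of the snapshot
#' correlation matrix \eqn{\int P(t) P(t)^T dt} belonging to its largest
#' eigenvalue. Computed by the method of snapshots: the K x K weighted
#' Gram matrix is diagonalized instead of the d x d correlation matrix.
#' The sign is fixed by making the largest-magnitude entry positive.
#'
#' @param trajectory a \code{full_trajectory} or a \code{d x K} snapshot
#'   matrix.
#' @param weights quadrature weights (taken from the trajectory's grid
#'   when omitted).
#' @return unit-norm numeric vector of length d.
#' @export
pod_first_mode <- function(trajectory, weights = NULL) {
  X <- snapshot_matrix(trajectory)
  w <- snapshot_weights(trajectory, weights)
  if (length(w) != ncol(X)) stop("weights length must equal snapshot count")
  if (all(X == 0)) stop("POD of an all-zero trajectory is undefined")
  Y <- X * rep(sqrt(w), each = nrow(X))    # C = Y Y^T
  G <- crossprod(Y)                        # K x K Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  z <- eg$vectors[, 1]
  v <- as.numeric(Y %*% z)
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate POD mode (zero leading eigenvector)")
  v <- v / nv
  imax <- which.max(abs(v))
  if (v[imax] < 0) v <- -v
  v
}

#' Time-integrated projection error of a trajectory on a basis
#'
#' Trapezoidal approximation of
#' \eqn{\int_0^T ||P(t) - V V^T P(t)||^2 dt}, the error indicator driving
#' the greedy basis selection.
#'
#' @param trajectory \code{full_trajectory} or snapshot matrix.
#' @param V orthonormal basis matrix (d x r); orthonormality is checked.
#' @param weights quadrature weights (from the grid when omitted).
#' @return nonnegative scalar.
#' @export
projection_error <- function(trajectory, V, weights = NULL) {
  X <- snapshot_matrix(trajectory)
  w <- snapshot_weights(trajectory, weights)
  V <- as.matrix(V)
  check_orthonormal(V)
  sum(w * residual_norms2(X, V))
}

# per-snapshot squared residual norms ||P_k - V V' P_k||^2 computed as
# ||P_k||^2 - ||V' P_k||^2; differences below the cancellation floor of
# that subtraction are reported as exact zeros
residual_norms2 <- function(X, V) {
  norms2 <- colSums(X^2)
  G <- crossprod(V, X)                     # r x K
  err <- pmax(norms2 - colSums(G^2), 0)
  err[err <= 1e-14 * norms2] <- 0
  err
}

check_orthonormal <- function(V, tol = 1e-8) {
  r <- ncol(V)
  if (r == 0L) return(invisible(TRUE))
  dev <- max(abs(crossprod(V) - diag(r)))
  if (dev > tol)
    stop("basis is not orthonormal (max |V'V - I| = ", signif(dev, 3), ")")
  invisible(TRUE)
}

# Gram-Schmidt of v against orthonormal V, two passes; returns the
# residual and its norm (norm ~ 0 means v is already in span(V)).
orthogonalize <- function(v, V) {
  for (pass in 1:2) {
    if (ncol(V) > 0L) v <- v - V %*% crossprod(V, v)
    v <- as.numeric(v)
  }
  list(v = v, norm = sqrt(sum(v^2)))
}

#' POD-Greedy reduced-basis training
#'
#' Incrementally grows an orthonormal basis from cached full-model
#' trajectories over a training parameter set: each iteration finds the
#' worst-approximated training parameter (largest projection error),
#' projects its trajectory onto the orthogonal complement of the current
#' basis, and appends the dominant POD mode of that error trajectory,
#' until the maximal training error drops below \code{eps_tol} or the
#' basis size cap is reached. Each full trajectory is simulated exactly
#' once and reused across iterations.
#'
#' @param trajectories list of \code{full_trajectory} objects on a
#'   common grid (one per training parameter), or NULL to have them
#'   simulated from \code{operator}/\code{P0}/\code{grid}.
#' @param operator,P0,grid,theta_train,fixed,solver_options used only when
#'   \code{trajectories} is NULL: the full model is solved at every row
#'   of \code{theta_train} (a matrix with named columns) on \code{grid};
#'   \code{solver_options} is a list passed to [solve_full()];
#'   \code{fixed} is a named list of non-varied parameters merged under
#'   every training row (e.g. a fixture's nominal values).
#' @param V_init initial orthonormal basis (d x N0 matrix or a single
#'   vector, normalized if needed). Typically the normalized initial
#'   distribution.
#' @param eps_tol training-error tolerance terminating the loop.
#' @param max_size hard cap on the basis size (guarantees termination).
#' @param cache_dir optional directory: full trajectories are stored as
#'   RDS files keyed by a hash of (operator, theta, grid) and reloaded
#'   instead of re-simulated.
#' @param verbose print one line per greedy iteration (N, theta*, eps_N).
#' @return Object of class \code{reduced_basis}: \code{V} (d x r),
#'   \code{report} (class \code{greedy_report}) with fields \code{eps}
#'   (the non-increasing training-error sequence, one entry per
#'   examined basis size), \code{basis_sizes}, \code{selected} (chosen
#'   training indices), \code{selected_theta}, \code{eps_tol},
#'   \code{status} (\code{"converged"}, \code{"max_size"} or
#'   \code{"stagnated"}), \code{elapsed}.
#' @export
pod_greedy <- function(trajectories = NULL, V_init, eps_tol = 1e-12,
                       max_size = 200L,
                       operator = NULL, P0 = NULL, grid = NULL,
                       theta_train = NULL, fixed = NULL,
                       solver_options = list(),
                       cache_dir = NULL, verbose = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  if (is.null(trajectories)) {
    if (is.null(operator) || is.null(P0) || is.null(grid) || is.null(theta_train))
      stop("either trajectories or (operator, P0, grid, theta_train) must be given")
    trajectories <- compute_training_trajectories(
      operator, P0, grid, theta_train, fixed, solver_options, cache_dir, verbose)
  }
  X <- lapply(trajectories, snapshot_matrix)
  w <- snapshot_weights(trajectories[[1]])
  theta_list <- lapply(trajectories, `[[`, "theta")

  V <- as.matrix(V_init)
  if (ncol(V) == 1L) V <- V / sqrt(sum(V^2))
  check_orthonormal(V, tol = 1e-8)
  d <- nrow(V)

  proj_err <- function(Vn) {
    vapply(seq_along(X), function(i) sum(w * residual_norms2(X[[i]], Vn)), 0)
  }

  eps_seq <- numeric(0)
  sizes <- integer(0)
  selected <- integer(0)
  status <- "max_size"
  repeat {
    errs <- proj_err(V)
    eps_N <- max(errs)
    eps_seq <- c(eps_seq, eps_N)
    sizes <- c(sizes, ncol(V))
    if (verbose)
      message(sprintf("POD-Greedy N = %3d  eps_N = %.3e", ncol(V), eps_N))
    if (eps_N <= eps_tol) { status <- "converged"; break }
    if (ncol(V) >= max_size) { status <- "max_size"; break }
    istar <- which.max(errs)            # ties: smallest training index
    selected <- c(selected, istar)
    E <- X[[istar]] - V %*% crossprod(V, X[[istar]])
    if (all(abs(E) < 1e-300)) { status <- "stagnated"; break }
    v_new <- pod_first_mode(E, weights = w)
    og <- orthogonalize(v_new, V)
    if (og$norm < 1e-10) {
      warning("POD-Greedy stagnated: appended mode already in span(V)")
      status <- "stagnated"; break
    }
    V <- cbind(V, og$v / og$norm)
  }
  report <- structure(
    list(eps = eps_seq, basis_sizes = sizes, selected = selected,
         selected_theta = theta_list[selected], eps_tol = eps_tol,
         n_train = length(X), status = status,
         elapsed = proc.time()[["elapsed"]] - t_start),
    class = "greedy_report")
  structure(list(V = V, report = report), class = "reduced_basis")
}

compute_training_trajectories <- function(operator, P0, grid, theta_train,
                                          fixed, solver_options, cache_dir,
                                          verbose) {
  if (is.null(dim(theta_train)))
    theta_train <- matrix(theta_train, ncol = 1,
                          dimnames = list(NULL, names(theta_train)))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  op_key <- model_hash(list(lapply(operator$components, function(m) c(m@i, m@p)),
                            grid$times))
  lapply(seq_len(nrow(theta_train)), function(i) {
    theta <- as.list(theta_train[i, ])
    if (!is.null(fixed))
      theta <- utils::modifyList(as.list(fixed), theta)  # varied values win
    key <- model_hash(list(op_key, theta))
    file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds"))
    if (!is.null(file) && file.exists(file)) return(readRDS(file))
    if (verbose) message("  simulating training parameter ", i, "/",
                         nrow(theta_train))
    tr <- do.call(solve_full, c(list(operator = operator, theta = theta,
                                     P0 = P0, grid = grid), solver_options))
    if (!is.null(file)) saveRDS(tr, file)
    tr
  })
}

# stable content hash without external digest packages
model_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # fold the serialized stream into a 64-bit-ish hex key
  ints <- as.integer(raw[seq(15, length(raw))])  # skip header
  acc <- c(0, 0)
  for (off in 0:1) {
    sub <- ints[seq(1 + off, length(ints), by = 2)]
    h <- 0
    for (chunk in split(sub, ceiling(seq_along(sub) / 4096))) {
      h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
    }
    acc[off + 1] <- h
  }
  sprintf("%08x%08x", acc[1], acc[2])
}

#' @exportS3Method base::print
print.reduced_basis <- function(x, ...) {
  r <- x$report
  cat("Reduced basis:", ncol(x$V), "orthonormal vectors in dimension",
      nrow(x$V), "\n")
  cat(sprintf("  POD-Greedy: %s after %d iterations, eps = %.3e (tol %.1e), %.1f s\n",
              r$status, length(r$eps) - 1L, r$eps[length(r$eps)], r$eps_tol,
              r$elapsed))
  invisible(x)
}

#' @exportS3Method base::print
print.greedy_report <- function(x, ...) {
  cat("POD-Greedy report:", x$status, "\n")
  print(data.frame(N = x$basis_sizes, eps_N = x$eps))
  invisible(x)
}

#' Project the full parametric model onto a reduced basis
#'
#' Galerkin projection with \eqn{W := V}: every operator component is
#' reduced to \eqn{A_r^{[q]} = V^T A^{[q]} V}, the output map to
#' \eqn{C_r = C V} and the initial condition to \eqn{P_{r0} = V^T P_0}.
#' All reduced pieces are r-dimensional and independent of d; the basis
#' itself is retained only for state reconstruction.
#'
#' @param po a [parametric_operator()].
#' @param output_map an output map (or NULL for state-only reduction).
#' @param P0 initial distribution (vector or \code{initial_distribution}).
#' @param V reduced basis: a \code{reduced_basis} or an orthonormal
#'   matrix.
#' @return Object of class \code{reduced_model} with fields \code{Ar}
#'   (list of dense r x r components), \code{coefs}, \code{labels},
#'   \code{Cr}, \code{output_labels}, \code{P0r}, \code{V},
#'   \code{domain}, \code{r}.
#' @export
reduce_model <- function(po, output_map = NULL, P0, V) {
  if (inherits(V, "reduced_basis")) V <- V$V
  V <- as.matrix(V)
  check_orthonormal(V)
  if (nrow(V) != po$ss$d) stop("basis dimension does not match operator")
  if (inherits(P0, "initial_distribution")) P0 <- P0$P0
  Ar <- lapply(po$components, function(Aq) as.matrix(crossprod(V, Aq %*% V)))
  Cr <- NULL; out_labels <- NULL
  if (!is.null(output_map)) {
    C <- if (inherits(output_map, "output_map")) output_map$C else output_map
    if (ncol(C) != nrow(V)) stop("output map dimension does not match basis")
    Cr <- as.matrix(C %*% V)
    out_labels <- if (inherits(output_map, "output_map")) output_map$labels
  }
  structure(list(Ar = Ar, coefs = po$coefs, labels = po$labels,
                 Cr = Cr, output_labels = out_labels,
                 P0r = as.numeric(crossprod(V, P0)),
                 V = V, domain = po$domain, r = ncol(V), Q = po$Q),
            class = "reduced_model")
}

#' @exportS3Method base::print
print.reduced_model <- function(x, ...) {
  cat("Reduced CME model: r =", x$r, "modes,", x$Q, "components",
      if (!is.null(x$Cr)) paste0(", ", nrow(x$Cr), " output(s)"), "\n")
  invisible(x)
}

#' Assemble the reduced operator at a parameter vector
#' @param rm a \code{reduced_model}.
#' @param theta named parameter vector.
#' @return dense r x r matrix \eqn{A_r(\theta)}.
#' @export
assemble_reduced <- function(rm, theta) {
  theta <- as.list(theta)
  A <- matrix(0, rm$r, rm$r)
  for (q in seq_len(rm$Q)) A <- A + rm$coefs[[q]](theta) * rm$Ar[[q]]
  A
}

#' Solve the reduced model (online phase)
#'
#' Assembles \eqn{A_r(\theta)} and integrates the r-dimensional system
#' \eqn{dP_r/dt = A_r(\theta) P_r}, \eqn{P_r(0) = P_{r0}}, returning the
#' reduced states and the approximate outputs
#' \eqn{\hat y(t) = C_r P_r(t)}. The default propagator is the exact
#' dense matrix exponential per grid interval (cached per distinct step
#' length), which is robust at any stiffness for the small reduced
#' systems; \code{"lsoda"} uses an adaptive ODE solver instead.
#'
#' @param rm a \code{reduced_model}.
#' @param theta named parameter vector (checked against the admissible
#'   domain; use \code{extrapolate = TRUE} to demote the check to a
#'   warning).
#' @param grid a [time_grid()].
#' @param method \code{"expm"} (default) or \code{"lsoda"}.
#' @param extrapolate allow parameters outside the trained domain.
#' @return Object of class \code{reduced_trajectory}: \code{grid},
#'   \code{Pr} (r x K), \code{y} (outputs x K, when the model has an
#'   output map), \code{theta}.
#' @export
solve_reduced <- function(rm, theta, grid, method = c("expm", "lsoda"),
                          extrapolate = FALSE, rtol = 1e-10, atol = 1e-12) {
  method <- match.arg(method)
  check_domain(rm$domain, as.list(theta),
               action = if (extrapolate) "warn" else "error")
  A <- assemble_reduced(rm, theta)
  times <- grid$times
  K <- length(times)
  Pr <- matrix(0, rm$r, K)
  Pr[, 1] <- rm$P0r
  if (method == "expm") {
    cache <- list()
    for (k in seq_len(K - 1L)) {
      h <- times[k + 1L] - times[k]
      key <- sprintf("%.17g", h)
      if (is.null(cache[[key]]))
        cache[[key]] <- as.matrix(Matrix::expm(h * A))
      Pr[, k + 1L] <- cache[[key]] %*% Pr[, k]
    }
  } else {
    sol <- deSolve::lsoda(y = rm$P0r, times = times,
                          func = function(t, y, p) list(as.numeric(A %*% y)),
                          rtol = rtol, atol = atol)
    Pr <- t(unname(sol[, -1, drop = FALSE]))
  }
  y <- if (!is.null(rm$Cr)) {
    out <- rm$Cr %*% Pr
    rownames(out) <- rm$output_labels
    out
  }
  structure(list(grid = grid, Pr = Pr, y = y, theta = theta),
            class = "reduced_trajectory")
}

#' Reconstruct approximate full states from a reduced trajectory
#'
#' Lifts the reduced states back to the lattice: \eqn{\hat P(t) = V P_r(t)}.
#'
#' @param V a \code{reduced_basis}, \code{reduced_model} or basis matrix.
#' @param reduced a \code{reduced_trajectory} or an r x K matrix.
#' @return d x K matrix of approximate probability snapshots.
#' @export
reconstruct <- function(V, reduced) {
  if (inherits(V, "reduced_basis")) V <- V$V
  if (inherits(V, "reduced_model")) V <- V$V
  Pr <- if (inherits(reduced, "reduced_trajectory")) reduced$Pr else as.matrix(reduced)
  if (ncol(V) != nrow(Pr)) stop("basis and reduced states disagree on r")
  as.matrix(V %*% Pr)
}
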