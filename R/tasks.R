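# Parametric analyses on reduced models: synthetic noisy measurements,
# least-squares cost, bound-constrained estimation, cost landscapes and
# sensitivity sweeps.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic noisy measurement of an output trajectory
#'
#' Applies multiplicative white noise to a clean output series:
#' \eqn{y_{meas}(t_k) = y(t_k)(1 + level \cdot n_k)} with i.i.d. standard
#' normal \eqn{n_k} from a seeded generator (the seed is recorded so the
#' measurement is exactly reproducible; the global RNG state is left
#' untouched).
#'
#' @param y numeric vector of clean output values at the grid times (or
#'   a 1-row matrix from [observe()]).
#' @param grid the [time_grid()] the values live on.
#' @param level relative noise level (e.g. 0.05 for 5\%); 0 gives the
#'   clean signal back.
#' @param seed integer RNG seed, mandatory for level > 0.
#' @param theta_ref optional generating parameter vector, recorded for
#'   self-consistency checks.
#' @return Object of class \code{measurement}: \code{grid}, \code{y}
#'   (clean), \code{y_meas}, \code{level}, \code{seed}, \code{theta_ref}.
#' @export
add_noise <- function(y, grid, level, seed = NULL, theta_ref = NULL) {
  y <- as.numeric(y)
  if (length(y) != length(grid$times))
    stop("output series length does not match grid")
  if (level < 0) stop("noise level must be nonnegative")
  if (level > 0 && is.null(seed)) stop("a seed is required for noisy measurements")
  y_meas <- if (level == 0) y else
    with_seed(seed, y * (1 + level * stats::rnorm(length(y))))
  structure(list(grid = grid, y = y, y_meas = y_meas, level = level,
                 seed = seed, theta_ref = theta_ref),
            class = "measurement")
}

solve_output <- function(rm, theta, grid, output = 1L, extrapolate = FALSE) {
  tr <- solve_reduced(rm, theta, grid, extrapolate = extrapolate)
  if (is.null(tr$y)) stop("reduced model has no output map")
  as.numeric(tr$y[output, ])
}

#' Least-squares data-misfit cost
#'
#' Trapezoidal quadrature of the squared residual between the measured
#' output and the reduced model's prediction:
#' \eqn{J(\theta) = \int_0^T (y_{meas}(t) - \hat y(t, \theta))^2 dt},
#' evaluated on the measurement grid.
#'
#' @param rm a \code{reduced_model}.
#' @param theta named parameter vector.
#' @param measurement a [add_noise()] measurement.
#' @param output row index of the model output to fit (default 1).
#' @param extrapolate allow theta outside the trained domain.
#' @return nonnegative scalar \eqn{J(\theta)}.
#' @export
cost <- function(rm, theta, measurement, output = 1L, extrapolate = FALSE) {
  yhat <- solve_output(rm, theta, measurement$grid, output, extrapolate)
  sum(measurement$grid$weights * (measurement$y_meas - yhat)^2)
}

#' Least-squares parameter estimation on the reduced model
#'
#' Minimizes [cost()] over a box (optionally with some parameters held
#' fixed, e.g. a 1-D restriction along one parameter axis) with the
#' bound-constrained quasi-Newton optimizer \code{optim(method =
#' "L-BFGS-B")}. The start defaults to the box midpoint. Optimizer
#' failure is reported in the result status, not thrown.
#'
#' @param rm a \code{reduced_model}.
#' @param measurement the data to fit.
#' @param lower,upper named vectors bounding the free parameters.
#' @param fixed named vector of parameters held at given values.
#' @param start optional named start values for the free parameters.
#' @param output output row to fit.
#' @param control \code{optim} control list (default
#'   \code{list(factr = 1e7)}).
#' @return Object of class \code{estimation_result}: \code{theta_est}
#'   (all parameters, free and fixed), \code{J_est}, \code{J_ref} (cost
#'   at the measurement's generating parameters, when recorded),
#'   \code{evaluations}, \code{convergence}, \code{message}.
#' @export
estimate <- function(rm, measurement, lower, upper, fixed = NULL,
                     start = NULL, output = 1L, control = list(factr = 1e7)) {
  free <- names(lower)
  if (!identical(free, names(upper))) stop("lower/upper names must agree")
  if (is.null(start)) start <- (lower + upper) / 2
  start <- start[free]
  n_eval <- 0L
  fn <- function(par) {
    n_eval <<- n_eval + 1L
    theta <- c(as.list(stats::setNames(par, free)), as.list(fixed))
    cost(rm, theta, measurement, output = output)
  }
  # finite-difference steps must live on the parameter scale: optimize
  # over box-normalized coordinates in [0, 1]
  span <- upper - lower
  if (any(span <= 0)) stop("upper must exceed lower for every free parameter")
  fn_unit <- function(z) fn(lower + z * span)
  if (is.null(control$ndeps)) control$ndeps <- rep(1e-6, length(span))
  opt <- tryCatch(
    stats::optim((start - lower) / span, fn_unit, method = "L-BFGS-B",
                 lower = rep(0, length(span)), upper = rep(1, length(span)),
                 control = control),
    error = function(e) list(par = (start - lower) / span, value = fn(start),
                             convergence = 99L, message = conditionMessage(e)))
  par_est <- lower + opt$par * span
  theta_est <- c(as.list(stats::setNames(par_est, free)), as.list(fixed))
  J_ref <- if (!is.null(measurement$theta_ref))
    cost(rm, measurement$theta_ref, measurement, output = output)
  structure(list(theta_est = theta_est, J_est = opt$value, J_ref = J_ref,
                 evaluations = n_eval, convergence = opt$convergence,
                 message = opt$message, free = free, fixed = fixed),
            class = "estimation_result")
}

#' @exportS3Method base::print
print.estimation_result <- function(x, ...) {
  est <- unlist(x$theta_est[x$free])
  cat("Parameter estimate:", paste(sprintf("%s = %.6g", names(est), est),
                                   collapse = ", "), "\n")
  cat(sprintf("  J(theta_est) = %.6g (%d cost evaluations, convergence %d)\n",
              x$J_est, x$evaluations, x$convergence))
  if (!is.null(x$J_ref)) cat(sprintf("  J(theta_ref) = %.6g\n", x$J_ref))
  invisible(x)
}

#' Cost landscape over a parameter grid
#'
#' Evaluates the least-squares cost at every node of a tensor grid of
#' parameter values via the reduced model (e.g. a 21 x 21 grid gives 441
#' fast online solves). Nodes outside the admissible domain are rejected
#' up front.
#'
#' @param rm a \code{reduced_model}.
#' @param measurement the data.
#' @param values named list of per-parameter value vectors.
#' @param fixed named vector of parameters held fixed.
#' @param output output row to fit.
#' @return data.frame with one column per swept parameter plus \code{J};
#'   rows in lexicographic order, first parameter varying fastest.
#' @export
cost_landscape <- function(rm, measurement, values, fixed = NULL, output = 1L) {
  for (nm in names(values)) {
    rng <- rm$domain[[nm]]
    if (!is.null(rng) && (min(values[[nm]]) < rng[1] || max(values[[nm]]) > rng[2]))
      stop("landscape values for ", nm, " leave the admissible domain")
  }
  grid_df <- expand.grid(values, KEEP.OUT.ATTRS = FALSE)
  J <- vapply(seq_len(nrow(grid_df)), function(i) {
    theta <- c(as.list(grid_df[i, , drop = FALSE]), as.list(fixed))
    cost(rm, theta, measurement, output = output)
  }, 0)
  grid_df$J <- J
  grid_df
}

#' Sensitivity sweep of a region probability over one parameter
#'
#' Solves the reduced model at each parameter value and records a region
#' probability (a 0/1 output row, e.g. \code{Prob(x2 > 100)}) at the
#' evaluation time. Values outside the trained parameter range are
#' permitted with a warning (the reduced model is demonstrably able to
#' extrapolate somewhat beyond its training interval).
#'
#' @param rm a \code{reduced_model} whose output map contains the region
#'   row.
#' @param parameter name of the swept parameter.
#' @param values numeric vector of parameter values.
#' @param t_eval evaluation time (must lie on \code{[0, T]}; the
#'   probability is linearly interpolated between grid times).
#' @param grid the [time_grid()] to integrate on.
#' @param fixed named vector of the remaining parameters.
#' @param output row index of the region output (default 1).
#' @return data.frame with columns \code{value} and \code{prob}.
#' @export
sensitivity_sweep <- function(rm, parameter, values, t_eval, grid,
                              fixed = NULL, output = 1L) {
  if (t_eval < 0 || t_eval > grid$T) stop("t_eval outside the time grid")
  rng <- rm$domain[[parameter]]
  if (!is.null(rng) && (min(values) < rng[1] || max(values) > rng[2]))
    warning("sweep extrapolates beyond the trained range [",
            rng[1], ", ", rng[2], "] for ", parameter)
  prob <- vapply(values, function(val) {
    theta <- c(stats::setNames(list(val), parameter), as.list(fixed))
    tr <- suppressWarnings(solve_reduced(rm, theta, grid, extrapolate = TRUE))
    if (is.null(tr$y)) stop("reduced model has no output map")
    stats::approx(grid$times, as.numeric(tr$y[output, ]), xout = t_eval)$y
  }, 0)
  data.frame(value = values, prob = prob)
}
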