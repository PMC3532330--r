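#' Enumerate a rectangular truncated state space
#'
#' Builds the finite state projection lattice: all integer copy-number
#' vectors in the axis-aligned box \code{[lower, upper]}, enumerated in a
#' fixed lexicographic order with the first species varying fastest.
#' The resulting ordering defines the row/column indexing of every FSP
#' operator, output map and probability vector in the package.
#'
#' @param lower integer vector of per-species lower copy-number bounds.
#' @param upper integer vector of per-species upper bounds, \code{>= lower}.
#' @param species optional character vector of species names.
#' @return An object of class \code{state_space} with fields
#'   \code{lower}, \code{upper}, \code{sizes}, \code{d} (number of states),
#'   \code{states} (a \code{d x n} integer matrix, one state per row) and
#'   \code{strides} (used by the inverse index map).
#' @examples
#' ss <- state_space(c(0, 0), c(1, 1))
#' ss$states          # (0,0), (1,0), (0,1), (1,1)
#' state_index(ss, c(0, 1))
#' @export
state_space <- function(lower, upper, species = NULL) {
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  if (length(lower) == 0L || length(lower) != length(upper))
    stop("lower and upper must be nonempty vectors of equal length")
  if (any(lower < 0L)) stop("copy-number bounds must be nonnegative")
  if (any(upper < lower)) stop("upper bound below lower bound")
  n <- length(lower)
  if (is.null(species)) species <- paste0("x", seq_len(n))
  sizes <- upper - lower + 1L
  d <- prod(as.double(sizes))
  if (d > .Machine$integer.max) stop("state space too large to enumerate")
  d <- as.integer(d)
  # species 1 varies fastest: strides are cumulative products of sizes
  strides <- cumprod(c(1L, sizes[-n]))
  states <- matrix(0L, d, n, dimnames = list(NULL, species))
  for (k in seq_len(n)) {
    reps_each <- prod(as.double(c(1L, sizes)[seq_len(k)]))
    states[, k] <- lower[k] +
      rep(rep(seq_len(sizes[k]) - 1L, each = reps_each),
          length.out = d)
  }
  structure(
    list(lower = lower, upper = upper, sizes = sizes, d = d,
         species = species, strides = strides, states = states),
    class = "state_space")
}

#' Map lattice states to enumeration indices
#'
#' Inverse of the enumeration in [state_space()]: returns, for each state
#' (row of \code{x}), its 1-based index in \code{ss$states}, or \code{NA}
#' for points outside the box.
#'
#' @param ss a \code{state_space}.
#' @param x an integer vector (single state) or a matrix with one state
#'   per row.
#' @return Integer vector of indices in \code{1..d}, \code{NA} outside.
#' @export
state_index <- function(ss, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(ss$lower)) stop("state dimension mismatch")
  rel <- sweep(x, 2L, ss$lower)
  inside <- rowSums(rel < 0L) == 0L &
    rowSums(sweep(x, 2L, ss$upper, ">")) == 0L
  idx <- as.integer(1L + rel %*% ss$strides)
  idx[!inside] <- NA_integer_
  idx
}

#' @exportS3Method base::print
print.state_space <- function(x, ...) {
  cat("FSP state space:", length(x$lower), "species,",
      x$d, "states\n")
  cat("  box:", paste0("{", x$lower, "..", x$upper, "}", collapse = " x "),
      "\n")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.state_space <- function(x, ...) {
  data.frame(index = seq_len(x$d), x$states)
}
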