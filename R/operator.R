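#' Assemble one parameter-free FSP operator component
#'
#' Builds the sparse transition matrix of a single separable propensity
#' term on a truncated lattice. Column j carries the outflow of state
#' \eqn{x^{(j)}}: the diagonal entry is \eqn{-g(x^{(j)})}, and the inflow
#' entry \eqn{(i, j)} equals \eqn{g(x^{(j)})} exactly when
#' \eqn{x^{(i)} = x^{(j)} + v} lies inside the box. Outflow is counted
#' even when the reaction target leaves the truncation domain, so
#' probability leaks at the boundary (sink-type finite state projection);
#' column sums are 0 for interior states and negative where the reaction
#' exits the box.
#'
#' @param ss a [state_space()].
#' @param v integer net-change vector of the reaction.
#' @param g state function (vectorized over rows of a states matrix).
#' @return a \code{dgCMatrix} of dimension \code{d x d}.
#' @examples
#' ss <- state_space(0, 1)
#' as.matrix(assemble_component(ss, 1L, function(s) rep(1, nrow(s))))
#' @export
assemble_component <- function(ss, v, g) {
  v <- as.integer(v)
  if (length(v) != length(ss$lower))
    stop("net-change vector length does not match state space dimension")
  gv <- g(ss$states)
  if (any(!is.finite(gv)) || any(gv < 0))
    stop("state function returned negative or non-finite propensities")
  targets <- state_index(ss, sweep(ss$states, 2L, v, "+"))
  inside <- !is.na(targets) & gv != 0
  src <- which(inside)
  Matrix::sparseMatrix(
    i = c(targets[src], seq_len(ss$d)),
    j = c(src, seq_len(ss$d)),
    x = c(gv[src], -gv),
    dims = c(ss$d, ss$d))
}

#' Build the parameter-separable FSP operator of a network
#'
#' Assembles one sparse component per propensity term, so that the full
#' transition matrix is
#' \eqn{A(\theta) = \sum_q \vartheta^{[q]}(\theta) A^{[q]}} with
#' parameter-free components and scalar coefficient functions. The
#' expensive component assembly happens once; [assemble_operator()] then
#' combines the components for any admissible parameter vector.
#'
#' @param network a [reaction_network()].
#' @param ss a [state_space()] (one dimension per network species).
#' @param domain optional named list of \code{c(lower, upper)} admissible
#'   ranges for the varied parameters; parameters absent from the list
#'   are unconstrained.
#' @return Object of class \code{parametric_operator}: fields
#'   \code{components} (list of \code{dgCMatrix}), \code{coefs} (list of
#'   coefficient functions), \code{labels}, \code{Q}, \code{ss},
#'   \code{domain}.
#' @export
parametric_operator <- function(network, ss, domain = NULL) {
  if (length(network$species) != length(ss$lower))
    stop("network and state space disagree on species count")
  comps <- vector("list", length(network$propensities))
  coefs <- vector("list", length(network$propensities))
  labels <- character(length(network$propensities))
  for (q in seq_along(network$propensities)) {
    term <- network$propensities[[q]]
    v <- network$reactions[[term$reaction]]$net
    comps[[q]] <- assemble_component(ss, v, term$g)
    coefs[[q]] <- term$coef
    labels[q] <- term$label
  }
  structure(list(components = comps, coefs = coefs, labels = labels,
                 Q = length(comps), ss = ss, domain = domain),
            class = "parametric_operator")
}

check_domain <- function(domain, theta, action = c("error", "warn")) {
  action <- match.arg(action)
  if (is.null(domain)) return(invisible(TRUE))
  for (nm in names(domain)) {
    if (is.null(theta[[nm]])) next
    rng <- domain[[nm]]
    val <- theta[[nm]]
    if (val < rng[1] || val > rng[2]) {
      msg <- sprintf("parameter %s = %g outside admissible range [%g, %g]",
                     nm, val, rng[1], rng[2])
      if (action == "error") stop(msg, call. = FALSE)
      warning(msg, " (extrapolating beyond the trained range)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Evaluate the separable operator at a parameter vector
#'
#' Returns \eqn{A(\theta) = \sum_q \vartheta^{[q]}(\theta) A^{[q]}} as a
#' sparse matrix. Parameters outside the operator's admissible domain are
#' rejected.
#'
#' @param po a [parametric_operator()].
#' @param theta named numeric vector (or list) of parameter values.
#' @return a \code{dgCMatrix}.
#' @export
assemble_operator <- function(po, theta) {
  theta <- as.list(theta)
  check_domain(po$domain, theta)
  A <- NULL
  for (q in seq_len(po$Q)) {
    w <- po$coefs[[q]](theta)
    if (!is.finite(w) || w < 0)
      stop("coefficient function '", po$labels[q],
           "' returned a negative or non-finite value")
    Aq <- if (w == 0) NULL else w * po$components[[q]]
    if (!is.null(Aq)) A <- if (is.null(A)) Aq else A + Aq
  }
  if (is.null(A))
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(po$ss$d, po$ss$d))
  methods::as(A, "CsparseMatrix")
}

#' @exportS3Method base::print
print.parametric_operator <- function(x, ...) {
  cat("Parameter-separable FSP operator:", x$Q, "components on",
      x$ss$d, "states\n")
  nnz <- vapply(x$components, function(m) length(m@x), 0)
  cat("  components:", paste(sprintf("%s (%d nnz)", x$labels, nnz),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Expectation output map
#'
#' Builds the output matrix whose rows hold the species copy numbers, so
#' that \eqn{y(t) = C P(t)} is the vector of expected copy numbers.
#'
#' @param ss a [state_space()].
#' @param species species names or indices (default: all).
#' @return Object of class \code{output_map}: sparse matrix \code{C}
#'   (p x d), \code{labels}, \code{kind}.
#' @export
output_expectation <- function(ss, species = NULL) {
  if (is.null(species)) species <- ss$species
  idx <- if (is.character(species)) match(species, ss$species) else as.integer(species)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(ss$species)))
    stop("unknown species in expectation output")
  C <- methods::as(Matrix::Matrix(t(ss$states[, idx, drop = FALSE]),
                                  sparse = TRUE), "CsparseMatrix")
  structure(list(C = C, labels = paste0("E[", ss$species[idx], "]"),
                 kind = "expectation", ss = ss),
            class = "output_map")
}

#' Region-probability output map
#'
#' A single 0/1-valued output row summing the probability mass of a state
#' region, e.g. \code{Prob(x2 > 100)}.
#'
#' @param ss a [state_space()].
#' @param predicate function of the states matrix returning a logical
#'   vector selecting the region.
#' @param label output label.
#' @export
output_region <- function(ss, predicate, label = "Prob(region)") {
  sel <- predicate(ss$states)
  if (length(sel) != ss$d || !is.logical(sel))
    stop("region predicate must return one logical per state")
  C <- Matrix::sparseMatrix(i = rep(1L, sum(sel)), j = which(sel),
                            x = 1, dims = c(1L, ss$d))
  structure(list(C = C, labels = label, kind = "region_probability", ss = ss),
            class = "output_map")
}

#' Stack several output maps into one
#' @param ... output_map objects over the same state space.
#' @export
output_stack <- function(...) {
  maps <- list(...)
  structure(list(C = do.call(rbind, lapply(maps, `[[`, "C")),
                 labels = unlist(lapply(maps, `[[`, "labels")),
                 kind = "custom", ss = maps[[1]]$ss),
            class = "output_map")
}

#' Uniform initial distribution on a state region
#'
#' Places mass \code{1/|support|} on every lattice state selected by the
#' predicate (e.g. all states with \code{x1 + x2 <= 20}, or a rectangle of
#' lower states); the support cardinality is counted on the actual
#' lattice, so the distribution always sums to exactly 1.
#'
#' @param ss a [state_space()].
#' @param predicate function of the states matrix returning a logical
#'   selection; must select at least one state.
#' @return Object of class \code{initial_distribution}: dense vector
#'   \code{P0} of length d plus a support description.
#' @export
initial_uniform <- function(ss, predicate, description = "uniform on predicate") {
  sel <- predicate(ss$states)
  ns <- sum(sel)
  if (ns == 0L) stop("initial-distribution predicate selects no state")
  P0 <- numeric(ss$d)
  P0[sel] <- 1 / ns
  structure(list(P0 = P0, support_size = ns, description = description, ss = ss),
            class = "initial_distribution")
}
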