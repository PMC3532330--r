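#' Define a stochastic reaction network
#'
#' A network is a list of species and reactions
#' \eqn{\sum_i \sigma_{ij} X_i \to \sum_i \phi_{ij} X_i}, together with
#' parameter-separable propensity terms. Each reaction's net change is
#' \eqn{v_j = \phi_{\cdot j} - \sigma_{\cdot j}}; distinct reactions must
#' have distinct net-change vectors.
#'
#' @param species character vector of species names (length n).
#' @param reactions list of reactions; each a list with integer vectors
#'   \code{reactant} and \code{product} of length n (stoichiometric
#'   coefficients), and optionally a \code{name}.
#' @param propensities list of [propensity_term()] objects. Several terms
#'   may reference the same reaction (a single propensity may split into
#'   several parameter-separable terms).
#' @return Object of class \code{reaction_network}.
#' @seealso [propensity_term()], [mass_action_term()]
#' @export
reaction_network <- function(species, reactions, propensities) {
  n <- length(species)
  if (n == 0L) stop("at least one species required")
  reactions <- lapply(seq_along(reactions), function(j) {
    r <- reactions[[j]]
    reac <- as.integer(r$reactant)
    prod <- as.integer(r$product)
    if (length(reac) != n || length(prod) != n)
      stop("stoichiometry length must match species count in reaction ", j)
    if (any(reac < 0L) || any(prod < 0L))
      stop("stoichiometric coefficients must be nonnegative")
    list(reactant = reac, product = prod, net = prod - reac,
         name = if (is.null(r$name)) paste0("R", j) else r$name)
  })
  nets <- vapply(reactions, function(r) paste(r$net, collapse = ","), "")
  if (anyDuplicated(nets))
    stop("reactions must have pairwise distinct net change vectors")
  for (term in propensities) {
    if (!inherits(term, "propensity_term")) stop("propensities must be propensity_term objects")
    if (term$reaction < 1L || term$reaction > length(reactions))
      stop("propensity term references nonexistent reaction ", term$reaction)
  }
  structure(list(species = species, reactions = reactions,
                 propensities = propensities),
            class = "reaction_network")
}

#' One parameter-separable propensity term
#'
#' The propensity of reaction j is written as a sum of terms
#' \eqn{\vartheta^{[q]}(\theta)\, g_q(x)}, with a parameter-only
#' coefficient function and a state-only rate function. This separation
#' is what makes offline/online model reduction possible: each term
#' yields one parameter-free sparse operator component.
#'
#' @param reaction 1-based index of the reaction the term fires.
#' @param coef function of a named parameter vector returning a
#'   nonnegative scalar \eqn{\vartheta^{[q]}(\theta)}.
#' @param g function mapping a states matrix (one state per row) to a
#'   nonnegative vector \eqn{g_q(x)}.
#' @param label short identifier used in logs and component exports.
#' @export
propensity_term <- function(reaction, coef, g, label = NULL) {
  stopifnot(is.function(coef), is.function(g))
  structure(list(reaction = as.integer(reaction), coef = coef, g = g,
                 label = if (is.null(label)) paste0("q", reaction) else label),
            class = "propensity_term")
}

#' Mass-action propensity term
#'
#' Convenience constructor for law-of-mass-action kinetics: the state
#' function is the plain monomial \eqn{\prod_i x_i^{\sigma_{ij}}} in the
#' reactant stoichiometry (a modelling convention; combinatorial falling
#' factorials are not used) and the coefficient is a single named rate
#' constant.
#'
#' @param reaction reaction index.
#' @param rate name of the rate-constant parameter.
#' @param reactant reactant stoichiometry vector \eqn{\sigma_{\cdot j}}.
#' @param label optional label (defaults to the rate name).
#' @export
mass_action_term <- function(reaction, rate, reactant, label = rate) {
  force(rate)
  sigma <- as.integer(reactant)
  propensity_term(
    reaction,
    coef = function(theta) unname(theta[[rate]]),
    g = mass_action_g(sigma),
    label = label)
}

# monomial prod_i x_i^sigma_i evaluated over rows of a states matrix
mass_action_g <- function(sigma) {
  sigma <- as.integer(sigma)
  function(states) {
    if (is.vector(states)) states <- matrix(states, nrow = 1L)
    out <- rep(1, nrow(states))
    for (i in which(sigma > 0L)) out <- out * states[, i]^sigma[i]
    out
  }
}

#' Evaluate a propensity term's state function at one or more states
#'
#' Returns \eqn{g_q(x)}; for a mass-action term this is the monomial
#' \eqn{\prod_i x_i^{\sigma_{ij}}}. A negative value signals a malformed
#' state function and raises an error.
#'
#' @param term a [propensity_term()].
#' @param x state vector or matrix of states (rows).
#' @return numeric vector of nonnegative state-function values.
#' @export
evaluate_propensity <- function(term, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  val <- term$g(x)
  if (any(!is.finite(val)) || any(val < 0))
    stop("propensity term '", term$label, "' returned a negative or non-finite value")
  val
}

#' @exportS3Method base::print
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions,",
      length(x$propensities), "separable propensity terms\n")
  for (j in seq_along(x$reactions)) {
    r <- x$reactions[[j]]
    cat(sprintf("  %s: net change (%s)\n", r$name,
                paste(r$net, collapse = ",")))
  }
  invisible(x)
}
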