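# Packaged model fixtures: the bistable follicle switch, the stochastic
# genetic oscillator, and an analytically solvable birth-death model
# used as an oracle in tests.

new_cme_model <- function(name, network, ss, operator, P0, outputs,
                          params, varied, T_final, units, notes = NULL) {
  structure(list(name = name, network = network, ss = ss,
                 operator = operator, P0 = P0, outputs = outputs,
                 params = params, varied = varied, T_final = T_final,
                 units = units, notes = notes),
            class = "cme_model")
}

#' @exportS3Method base::print
print.cme_model <- function(x, ...) {
  cat("CME model fixture '", x$name, "': ", length(x$network$species),
      " species, ", x$operator$Q, " separable components, d = ", x$ss$d,
      "\n", sep = "")
  cat("  varied parameters:",
      paste(sprintf("%s in [%g, %g]", names(x$varied),
                    vapply(x$varied, `[`, 0, 1),
                    vapply(x$varied, `[`, 0, 2)), collapse = ", "), "\n")
  cat("  T =", x$T_final, x$units, "\n")
  invisible(x)
}

#' Bistable follicle-switch model
#'
#' Two mutually activating gene products X1, X2. Production of X1 has
#' propensity \eqn{u_1 (k_1 + V_1 x_2^3 / (M_1^3 + x_2^3))}, degradation
#' \eqn{u_1 x_1}; production of X2 has propensity
#' \eqn{u_2 V_2 x_1^3 / (M_2^3 + x_1^3)}, degradation \eqn{u_2 x_2}.
#' Nominal rates: k1 = 4, V1 = V2 = 75, M1 = M2 = 25,
#' u1 = u2 = 0.01 / min. The Hill thresholds M1, M2 sit in denominators
#' and are treated as fixed, which leaves a 5-component separable
#' decomposition with coefficient functions
#' (u1*k1, u1*V1, u1, u2*V2, u2) and state functions
#' (1, Hill(x2), x1, Hill(x1), x2). The turnover rates (u1, u2) are the
#' varied parameters on [0.005, 0.02]^2; they set both the on-state
#' expression level and the off-to-on switching kinetics. The initial
#' mass is spread uniformly over the lower-corner states x1 + x2 <= 20
#' and the default horizon is T = 1e7 min (roughly three off-state
#' half-lives). Default output: E[x1].
#'
#' @param bound upper copy-number bound per species (default 150, the
#'   full truncation \{0..150\}^2; smaller values give scaled-down
#'   variants for quick studies).
#' @param T_final time horizon (default 1e7 minutes).
#' @param init_variant \code{"count"} (default): uniform mass 1/231 on
#'   the 231 states with x1 + x2 <= 20; \code{"210"}: the variant with
#'   support x1 + x2 <= 19 (210 states, mass 1/210).
#' @return a \code{cme_model} fixture.
#' @export
build_switch <- function(bound = 150L, T_final = 1e7,
                         init_variant = c("count", "210")) {
  init_variant <- match.arg(init_variant)
  params <- list(k1 = 4, V1 = 75, M1 = 25, u1 = 0.01,
                 V2 = 75, M2 = 25, u2 = 0.01)
  hill3 <- function(M) { force(M); function(z) z^3 / (M^3 + z^3) }
  h1 <- hill3(params$M1); h2 <- hill3(params$M2)
  reactions <- list(
    list(reactant = c(0L, 0L), product = c(1L, 0L), name = "prod_X1"),
    list(reactant = c(1L, 0L), product = c(0L, 0L), name = "deg_X1"),
    list(reactant = c(0L, 0L), product = c(0L, 1L), name = "prod_X2"),
    list(reactant = c(0L, 1L), product = c(0L, 0L), name = "deg_X2"))
  props <- list(
    propensity_term(1L, function(th) th$u1 * th$k1,
                    function(s) rep(1, nrow(s)), "u1*k1"),
    propensity_term(1L, function(th) th$u1 * th$V1,
                    function(s) h1(s[, 2]), "u1*V1"),
    propensity_term(2L, function(th) th$u1,
                    function(s) s[, 1], "u1"),
    propensity_term(3L, function(th) th$u2 * th$V2,
                    function(s) h2(s[, 1]), "u2*V2"),
    propensity_term(4L, function(th) th$u2,
                    function(s) s[, 2], "u2"))
  net <- reaction_network(c("x1", "x2"), reactions, props)
  ss <- state_space(c(0L, 0L), c(bound, bound), species = c("x1", "x2"))
  varied <- list(u1 = c(0.005, 0.02), u2 = c(0.005, 0.02))
  po <- parametric_operator(net, ss, domain = varied)
  cutoff <- if (init_variant == "count") 20L else 19L
  P0 <- initial_uniform(ss, function(s) rowSums(s) <= cutoff,
                        paste0("uniform on x1 + x2 <= ", cutoff))
  outputs <- list(
    Ex1 = output_expectation(ss, "x1"),
    Ex = output_expectation(ss))
  new_cme_model("switch", net, ss, po, P0, outputs, params, varied,
                T_final, units = "min",
                notes = "bistable follicle switch; off-state near (0,0), on-state near (75,75)")
}

#' Stochastic genetic oscillator model
#'
#' Negative feedback between two gene products with positive
#' autoregulation of X2. Propensities: production of X1
#' \eqn{k_1 s^2 / (k_2 s + x_2)}, degradation \eqn{k_3 x_1}; production
#' of X2 \eqn{k_4 s + k_5 x_2^2 x_1 / (k_6 s^2 + x_2^2)} (two separable
#' terms sharing one stoichiometry), degradation \eqn{k_7 x_2}. The
#' scaling parameter s = 10 converts dimensionless concentrations to
#' copy numbers and sets the noise level. Nominal rates: k1 = 15,
#' k2 = 0.2, k3 = 1, k4 = 10, k5 = 100, k6 = 6.5, k7 = 100 (per second;
#' k2, k6, s appear in denominators and stay fixed). The separable
#' decomposition has 5 components with coefficients
#' (k1, k3, k4, k5, k7). The varied parameter is k4 on [10, 100], the
#' basal production rate of X2, which controls the oscillation
#' amplitude. Initial condition: uniform on \{0..50\}^2; horizon T = 6 s;
#' default output Prob(x2 > 100).
#'
#' @param s system-size scaling (default 10): maps the dimensionless
#'   concentrations of the underlying rate model to copy numbers, and
#'   thereby sets the noise level (larger s, more molecules, less
#'   noise). The truncation box, initial rectangle and region threshold
#'   all scale with s, so smaller values give faithful scaled-down
#'   variants of the same dynamics.
#' @param bound per-species truncation bound (default \code{30 * s}:
#'   at s = 10 the full \{0..300\}^2 lattice of 90601 states).
#' @param T_final time horizon (default 6 seconds).
#' @return a \code{cme_model} fixture.
#' @export
build_oscillator <- function(s = 10, bound = as.integer(30 * s), T_final = 6) {
  params <- list(k1 = 15, k2 = 0.2, k3 = 1, k4 = 10, k5 = 100,
                 k6 = 6.5, k7 = 100, s = s)
  k2 <- params$k2; k6 <- params$k6
  reactions <- list(
    list(reactant = c(0L, 0L), product = c(1L, 0L), name = "prod_X1"),
    list(reactant = c(1L, 0L), product = c(0L, 0L), name = "deg_X1"),
    list(reactant = c(0L, 0L), product = c(0L, 1L), name = "prod_X2"),
    list(reactant = c(0L, 1L), product = c(0L, 0L), name = "deg_X2"))
  props <- list(
    propensity_term(1L, function(th) th$k1,
                    function(st) s^2 / (k2 * s + st[, 2]), "k1"),
    propensity_term(2L, function(th) th$k3,
                    function(st) st[, 1], "k3"),
    propensity_term(3L, function(th) th$k4,
                    function(st) rep(s, nrow(st)), "k4"),
    propensity_term(3L, function(th) th$k5,
                    function(st) st[, 2]^2 * st[, 1] / (k6 * s^2 + st[, 2]^2),
                    "k5"),
    propensity_term(4L, function(th) th$k7,
                    function(st) st[, 2], "k7"))
  net <- reaction_network(c("x1", "x2"), reactions, props)
  ss <- state_space(c(0L, 0L), c(bound, bound), species = c("x1", "x2"))
  varied <- list(k4 = c(10, 100))
  po <- parametric_operator(net, ss, domain = varied)
  init_hi <- as.integer(5 * s)
  thresh <- 10 * s
  P0 <- initial_uniform(ss, function(st) st[, 1] <= init_hi & st[, 2] <= init_hi,
                        paste0("uniform on {0..", init_hi, "}^2"))
  outputs <- list(
    Pburst = output_region(ss, function(st) st[, 2] > thresh,
                           paste0("Prob(x2 > ", thresh, ")")),
    Ex = output_expectation(ss))
  new_cme_model("oscillator", net, ss, po, P0, outputs, params, varied,
                T_final, units = "s",
                notes = "noise-induced oscillations; amplitude decays with k4")
}

#' Birth-death model with closed-form solution
#'
#' One species with constant birth (rate k) and first-order degradation
#' (rate gamma). Starting from an empty state the exact distribution at
#' time t is Poisson with mean \eqn{\lambda(t) = (k/\gamma)(1 -
#' e^{-\gamma t})} (or \eqn{k t} for \eqn{\gamma = 0}), which the
#' attached \code{poisson_lambda} function returns — an analytic oracle
#' for solver validation.
#'
#' @param k birth rate (> 0).
#' @param gamma degradation rate constant (>= 0).
#' @param bound truncation bound.
#' @return a \code{cme_model} with an extra \code{poisson_lambda(t)}
#'   element.
#' @export
build_birth_death <- function(k = 10, gamma = 1, bound = 60L) {
  if (k < 0 || gamma < 0) stop("rates must be nonnegative")
  reactions <- list(
    list(reactant = 0L, product = 1L, name = "birth"),
    list(reactant = 1L, product = 0L, name = "death"))
  props <- list(
    mass_action_term(1L, "k", 0L, "k"),
    mass_action_term(2L, "gamma", 1L, "gamma"))
  net <- reaction_network("x1", reactions, props)
  ss <- state_space(0L, bound, species = "x1")
  po <- parametric_operator(net, ss)
  P0 <- initial_uniform(ss, function(s) s[, 1] == 0L, "point mass at 0")
  model <- new_cme_model("birth_death", net, ss, po, P0,
                         list(Ex = output_expectation(ss)),
                         params = list(k = k, gamma = gamma),
                         varied = list(), T_final = 5, units = "a.u.")
  model$poisson_lambda <- function(t)
    if (gamma > 0) (k / gamma) * (1 - exp(-gamma * t)) else k * t
  model
}

#' Complete a parameter vector with a fixture's nominal values
#'
#' Fixture coefficient functions expect the full named parameter list;
#' this merges user-supplied values (typically just the varied
#' parameters) over the nominal table.
#'
#' @param model a \code{cme_model}.
#' @param theta named vector/list of overrides (may be NULL).
#' @return named list of all model parameters.
#' @export
model_params <- function(model, theta = NULL) {
  if (is.null(theta)) return(model$params)
  utils::modifyList(model$params, as.list(theta))
}

#' Directly assembled (non-separated) operator of a model
#'
#' Reference assembly that bypasses the separable decomposition: every
#' propensity term is evaluated with the parameters substituted,
#' yielding one sparse matrix. Used to cross-check that
#' \eqn{\sum_q \vartheta^{[q]}(\theta) A^{[q]}} reproduces the operator
#' entrywise.
#'
#' @param model a \code{cme_model} (or pass \code{network}, \code{ss}).
#' @param theta parameter values (defaults to the fixture nominals).
#' @return sparse \code{dgCMatrix}.
#' @export
direct_operator <- function(model, theta = NULL) {
  theta <- model_params(model, theta)
  net <- model$network; ss <- model$ss
  A <- NULL
  for (term in net$propensities) {
    v <- net$reactions[[term$reaction]]$net
    g_eval <- term$g
    w <- term$coef(theta)
    comp <- assemble_component(ss, v, function(s) w * g_eval(s))
    A <- if (is.null(A)) comp else A + comp
  }
  methods::as(A, "CsparseMatrix")
}
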