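---
title: "Reduced-order parametric analysis of chemical master equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order parametric analysis of chemical master equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmerb)
```

## The model class

A stochastic reaction network with species $X_1,\dots,X_n$ and reactions
$\sum_i \sigma_{ij} X_i \to \sum_i \phi_{ij} X_i$ induces a Markov jump
process on copy-number states $x \in \mathbb{N}_0^n$. The chemical master
equation (CME) governs the state probabilities $p(t,x)$:

$$\frac{d}{dt} p(t,x) \;=\; \sum_{j=1}^m \big( \nu_j(x - v_j,\theta)\,
p(t,x-v_j) - \nu_j(x,\theta)\, p(t,x) \big),$$

with net-change vectors $v_j = \phi_{\cdot j} - \sigma_{\cdot j}$ and
propensities $\nu_j(x,\theta)$. Probability flows *into* $x$ from the
source state $x - v_j$, at the propensity evaluated at the source: this is
how `assemble_component()` places its off-diagonal entries, and it is the
only convention under which the operator's columns sum to zero for
interior states. Mass-action propensities are rate constants times plain
monomials $\prod_i x_i^{\sigma_{ij}}$ in the copy numbers; we adopt the
plain-power convention (not falling factorials) as a modelling choice,
and document per fixture where Hill-type saturation terms replace
monomials.

The finite state projection (FSP) truncates the lattice to a rectangle
$\Omega = \{x^{(i)}\}_{i=1}^d$ and solves the linear ODE
$\dot P = A(\theta) P$, $P(0) = P_0$ on it. We enumerate $\Omega$
lexicographically with the first species varying fastest — an arbitrary
but fixed convention that every matrix in the package shares. Reactions
that would leave $\Omega$ still drain their source state (sink-type
truncation), so the total mass $\mathbf{1}^\top P(t)$ is non-increasing;
the mass deficit is itself a useful FSP-quality diagnostic, and tests
assert the monotonicity. We deliberately do not implement reflecting
boundaries or the classical FSP error bound; truncation adequacy is
judged by the retained mass.

Outputs are linear functionals $y(t) = C P(t)$: expectation rows carry
the state coordinates, region rows are 0/1 indicators (e.g.
$\mathrm{Prob}(x_2 > 100)$). Initial conditions are uniform
distributions on a predicate-selected support, normalized by the actual
support cardinality so they always sum to one exactly. For the switch
fixture the documented support is $x_1 + x_2 \le 20$, which on the full
lattice contains 231 states; a `"210"` variant with support
$x_1 + x_2 \le 19$ (210 states) is provided because both normalizations
circulate for this model.

## Parameter separability and the offline/online split

All propensities in scope factor into a parameter-only coefficient and a
state-only rate, so the operator decomposes as

$$A(\theta) = \sum_{q=1}^{Q_A} \vartheta^{[q]}(\theta)\, A^{[q]},$$

with parameter-free sparse components assembled once. Coefficients may
be products of parameters (the switch production term contributes
$u_1 k_1$ and $u_1 V_1$) and one reaction may contribute several
components (the oscillator's production of $X_2$ splits into a basal and
an autoregulatory term); both generalizations are exercised by the
fixtures. Parameters that appear inside denominators (Hill thresholds
$M_1, M_2$; the oscillator's $k_2, k_6, s$) cannot be separated this way
and are held fixed at their nominal values — varying them would require
approximate separation techniques that are out of scope here.

Given an orthonormal basis $V \in \mathbb{R}^{d\times r}$ (with $W := V$,
so biorthogonality holds by construction), the Galerkin-reduced model

$$A_r^{[q]} = V^\top A^{[q]} V, \qquad C_r = C V, \qquad P_{r0} = V^\top P_0$$

is assembled once offline; online, for each new $\theta$, only
$r \times r$ objects are touched, so the per-parameter cost is
independent of $d$.

## POD-Greedy basis training

The basis is grown from full-model trajectories at a finite training set
$\mathcal{P}_{\mathrm{train}}$ (a log-equidistant tensor grid by
default, since the rates vary over decades). The error indicator is the
time-integrated projection error
$\Delta(\theta, V) = \int_0^T \lVert P(t,\theta) - V V^\top P(t,\theta)
\rVert^2\, dt$; each greedy iteration selects the worst-resolved
training parameter, forms the orthogonal-complement error trajectory,
and appends its dominant POD mode. Design choices worth knowing:

* **POD by the method of snapshots.** The dominant mode is computed from
  the $K \times K$ weighted Gram matrix of the snapshots, never the
  $d \times d$ correlation matrix; the equivalence of the two
  eigenproblems is a tested property.
* **Quadrature.** Time integrals use trapezoidal weights on the
  trajectory's output grid. The scheme is a package choice; basis sizes
  can shift by a vector or two under other quadratures, which is why
  small such differences should not be over-interpreted.
* **Snapshot grids must resolve the dynamics.** The greedy only sees the
  solution at the snapshot times. For strongly multiscale problems
  (the switch relaxes in minutes but transitions over $10^6$–$10^7$
  minutes) a uniform grid hides the fast transient, and the greedy then
  converges on a basis that interpolates the snapshots yet projects to
  visibly wrong reduced dynamics. Logarithmically spaced output grids
  (`time_grid(..., spacing = "log")`) are the default choice for the
  stiff fixtures throughout the package's own studies.
* **Initialization and numerics.** $V$ starts from the normalized
  initial distribution (the raw $P_0$ is not unit-norm). Appended modes
  are re-orthogonalized against the basis with two Gram–Schmidt passes;
  a residual below $10^{-10}$ terminates with a stagnation warning. Ties
  in the argmax break to the smallest training index. A hard size cap
  (default 200) guarantees termination alongside the tolerance
  $\varepsilon_{\mathrm{tol}}$.
* **Caching.** Each training trajectory is simulated exactly once;
  an optional on-disk cache keyed by (operator, parameter, grid) makes
  interrupted offline runs resumable.

The training error sequence $\varepsilon_N$ is non-increasing by
construction, and on the switch training runs its logarithm falls
roughly linearly with $N$ — the exponential decay expected when the
solution manifold has rapidly decaying Kolmogorov widths (the
quantitative convergence theory is not implemented here).

## Solvers

The full FSP system is integrated with the adaptive stiff multistep
method of `deSolve::lsodes`, with the operator itself supplied
column-wise as an analytic sparse Jacobian (defaults
`rtol = 1e-8`, `atol = 1e-12`). An alternative `"expm"` mode steps
between output times with a Krylov (Arnoldi) approximation of
$e^{\tau A} v$ with adaptive sub-stepping; it can win on very long
stiff horizons, but its attainable accuracy is floored by the subspace
dimension, so the stiff integrator remains the default and the
reference. Reduced systems are propagated by exact dense matrix
exponentials per grid interval (cached per distinct step length), which
is unconditionally stable at any stiffness for the small $r$; an
adaptive `"lsoda"` mode exists for cross-checking. Tiny negative
probabilities from floating point are clipped only in reported outputs,
never in the integrated state.

## Parametric analysis tasks

Synthetic measurements apply multiplicative Gaussian noise,
$y_{\mathrm{meas}}(t_k) = y(t_k)(1 + \mathrm{level} \cdot n_k)$, from a
mandatorily recorded seed. The least-squares cost
$J(\theta) = \int_0^T (y_{\mathrm{meas}} - \hat y(t,\theta))^2 dt$ is a
trapezoidal quadrature on the measurement grid (which defaults to the
simulation grid); `estimate()` minimizes it with the bound-constrained
quasi-Newton `optim(method = "L-BFGS-B")` from the box midpoint,
optionally along a one-parameter restriction. Cost landscapes evaluate
$J$ on a tensor grid through the reduced model; sensitivity sweeps
record a region probability at an evaluation time across a parameter
range. Sweeping beyond the trained interval is allowed with a warning
rather than an error — moderate extrapolation is demonstrably useful
for these models — and identical inputs plus seed give bit-identical
curves.

## The packaged fixtures and the scaled-down study conditions

`build_switch()` is a bistable two-gene activator pair (off-state near
the origin, on-state near (75, 75)); its varied parameters are the
turnover rates $(u_1, u_2) \in [0.005, 0.02]^2$ (per minute), horizon
$T = 10^7$ min, output $E[x_1]$. `build_oscillator()` is a noise-driven
negative-feedback oscillator whose varied parameter $k_4 \in [10, 100]$
(per second) sets the oscillation amplitude; horizon $T = 6$ s, output
$\mathrm{Prob}(x_2 > 10\,s)$. At full scale these live on
$151^2 = 22801$ and $301^2 = 90601$ states, and training their bases to
$\varepsilon_{\mathrm{tol}} = 10^{-12}$ is a multi-hour offline
computation — provided as `scripts/full_scale_basis.R`, deliberately
outside the test suite.

The package's own routine studies use scaled-down variants chosen once:

* **Switch:** $\{0..80\}^2$ ($d = 6561$), $T = 10^6$, a $3 \times 3$
  log-equidistant training grid, log-spaced output grid of 80 points
  from $t = 1$. This keeps the off-to-on transition and the boundary
  truncation effects while a full trajectory solves in seconds.
* **Oscillator:** rather than crudely shrinking the box (which bleeds
  essentially all probability through the boundary), the system-size
  parameter is lowered to $s = 3$: copy numbers, the initial rectangle
  and the burst threshold ($x_2 > 30$) all scale with $s$, giving the
  same oscillation physics at $d = 8281$ with a higher noise level.

The synthetic estimation study mirrors the full-scale setup: the
measurement is the full model's $E[x_1]$ at the reference parameters
$(u_1, u_2) = (0.01, 0.01)$ with 5% multiplicative noise, and $u_1$ is
recovered along the line $u_2 = 0.01$. What passing these scaled-down
studies shows is that the machinery — assembly, training, reduction,
estimation — is correct and that the surrogate is accurate at its own
scale; it does not certify the full-scale basis sizes or timings, which
only the long script reproduces.

## Known limitations

No stochastic-simulation (Gillespie) sampling, no adaptive or moving
truncations, no a-posteriori error estimators for the reduced outputs:
reduced-model quality is assessed by direct full-model spot checks.
Denominator parameters are frozen; estimating them would need
empirical-interpolation-style extensions. The Galerkin projection does
not enforce nonnegativity or mass conservation of reconstructed states;
both hold only to the approximation accuracy of the basis.

## A worked micro-example

```{r example, eval = FALSE}
model <- build_birth_death(k = 8, gamma = 1, bound = 40)
grid <- time_grid(4, n = 41)
train <- make_training_set(list(k = c(4, 16)), 5, spacing = "linear")
basis <- pod_greedy(operator = model$operator, P0 = model$P0, grid = grid,
                    theta_train = train, fixed = model$params,
                    V_init = model$P0$P0, eps_tol = 1e-12)
rmodel <- reduce_model(model$operator, model$outputs$Ex, model$P0, basis)
solve_reduced(rmodel, list(k = 11, gamma = 1), grid)$y[1, 41]  # ~ E[x](4)
```
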