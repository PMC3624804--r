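---
title: "Decomposed rate-parameter estimation for data-rich mass-action networks"
author: "spedre package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposed rate-parameter estimation for data-rich mass-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spedre)
```

## The estimation problem

A mass-action network over species $x_1,\dots,x_S$ with reactions
$r = 1,\dots,R$ and rate constants $k_1,\dots,k_P$ induces the ODE system

$$\frac{dx_i}{dt} = f_i(\bar x, \bar k)
  = \sum_{r \ni i} s_{ir}\, k_{p(r)} \prod_{u \in \mathrm{react}(r)} x_u,$$

where $s_{ir} \in \{-2,\dots,2\}$ is the signed stoichiometry of species
$i$ in reaction $r$.  The *degree* of an ODE is the number of reactions
touching its species — the number of terms on its right-hand side.  Given
observed concentrations $\hat x_{e,i}(t_j)$ for **every** species at every
timepoint of every experiment (the data-rich regime), the inverse problem
is to recover $\bar k$.

The classical ("primal") route minimizes the weighted simulate-and-match
objective

$$\mathrm{SSE}(\bar k) = \sum_{e,i,j} w_i \big(x_i(t_j;\bar k) -
  \hat x_{e,i}(t_j)\big)^2,$$

which requires a full ODE simulation per candidate vector and couples all
parameters in every term.  This package implements the alternative
("dual") route: fit splines through the observations, interpolate the
time derivatives, and penalize the violation of each ODE at each time
slice,

$$\varepsilon_{e,i,j}(\bar k) = \Big(f_i\big(\hat x_e(t_j), \bar k\big) -
  \widehat{\tfrac{dx_{e,i}}{dt}}\Big|_{t_j}\Big)^2 .$$

Because $f_i$ is evaluated at the *observed* concentrations, each
$\varepsilon_{e,i,j}$ depends only on the handful of parameters appearing
in species $i$'s ODE.  The terms are combined multiplicatively into a
product of functions, $\mathrm{POF} = \prod_{e,i,j} \varepsilon_{e,i,j}$,
which is decomposable and therefore amenable to inference on a factor
graph.  The product is an imperfect score — it collapses to zero if any
single term does, and its minimizer need not minimize parameter error —
so the package reports the numerically stable normalized log form
$\frac{1}{N}\sum \log\max(\varepsilon, \text{floor})$ and treats the
whole dual stage as a *starting-point generator* for local refinement,
not as the final estimate.

## Stage 1: discretized MAP inference

Each parameter's domain (default $[0.05, 1.05]$) is cut into equidistant
bins (default 10) represented by their midpoints.  For every factor
$\varepsilon_{e,i,j}$ a joint look-up table over the bins of its adjacent
parameters is pre-computed once:

$$T_{e,i,j}(\bar b) = C \exp\big(-\beta\,\varepsilon_{e,i,j}(\text{mid}(\bar
b))\big),$$

normalized to sum to one.  Because the mass-action right-hand side is
*linear* in the rate constants at fixed concentrations, each table is an
affine expression evaluated on a grid — a few vectorized array operations
per factor rather than a loop over cells.  The cell count is exactly
$\sum_f (\text{bins})^{\deg f}$: exponential in the network degree,
polynomial in species, timepoints and bins, which is the method's
defining cost profile and is asserted exactly in the tests.

**Boltzmann scale.** No temperature is prescribed for the weighting, so
the default is per-factor adaptive, $\beta_f = 1/\max(\mathrm{median}
(\varepsilon_f), 10^{-12})$, which keeps tables informative (neither flat
nor one-hot) across problem scales; a global numeric override is
available.  A consequence worth knowing: max-product inference on these
tables maximizes $\sum_f -\beta_f \varepsilon_f$, a *weighted-sum*
surrogate of the product objective.  On densely sampled data the two
agree (the truth bin dominates every factor); on very sparse grids (4-5
timepoints) they can disagree, which is why the shipped benchmarks use
the standard 11-point grid.

**Propagation.** Max-product loopy belief propagation runs over the
bipartite graph of parameter (variable) nodes and error-term (factor)
nodes, with one deliberate deviation from the textbook algorithm,
implemented as specified for this estimator: the message a variable sends
to a factor is its *current full belief*, without excluding the recipient
factor's own previous contribution (`standard_bp = TRUE` switches to the
textbook exclusion rule for comparison).  Factors are processed in a
fixed lexicographic (experiment, species, timepoint) order; messages are
computed in log space as max-marginalizations of the log table plus
incoming log beliefs, normalized by max-subtraction, and stored in the
recipient's message history; after each sweep every belief becomes the
normalized product of its stored messages (current-sweep messages,
Gauss–Seidel style — the buffering semantics were ambiguous and this
choice is documented here).  Convergence is declared when no normalized
message moves by more than `tol` (default $10^{-6}$, sup norm) between
sweeps, with a cap of `max_iter` (default 100) because loopy propagation
on cyclic graphs may oscillate; hitting the cap flags the result but is
not an error.  No damping is applied by default; a `damping` factor in
$[0,1)$ is exposed and is the first thing to try when the convergence
trace (`$message_trace`) oscillates — the full-belief variant amplifies
feedback on cycles, and on ring benchmarks where undamped propagation
cycles between near-tied bin assignments, moderate damping (0.3–0.5)
restores convergence in the packaged tests.  Ties in any argmax resolve
to the lowest bin index, making the whole stage deterministic.

**Degeneracy.** Equilibrium (constant) data carry no rate information
beyond flux ratios; the resulting beliefs are near-uniform and the fit
warns that parameters may be non-identifiable rather than failing.

## Stage 2: local refinement

The MAP bin midpoints seed a bounded Levenberg–Marquardt least-squares
fit of the primal residual vector $\sqrt{w_i}(x_i(t_j;\bar k) - \hat
x_{e,i,j})$ (`minpack.lm::nls.lm`, finite-difference Jacobian).  Choices
the problem statement left open:

* **Weights.** $w_i = 1/\max_{e,j}(\hat x_{e,i,j})^2$, normalizing
  species to comparable scales (uniform weights available).  The weight
  is per species, shared across experiments.
* **Bounds.** The discretization bounds expanded by one bin width on each
  side (floored at zero), so refinement can leave the grid but not the
  modelled regime.
* **Initial conditions** for every simulation are the observed $t_0$
  values; they are not fitted.
* **Integrator failures** at wild candidate vectors return a large finite
  penalty residual instead of throwing, so the optimizer can back off.
* The refined objective never exceeds the starting one: if the solver
  fails to improve, the start vector is returned unchanged.

Trajectories are integrated with `deSolve::lsoda` at rtol $10^{-8}$ /
atol $10^{-10}$, so data-generation and fitting error are dominated by
estimation error, not the integrator.

## Splines and derivative estimation

The default derivative estimator is the interpolating natural cubic
spline (`smoothing = 0`): it passes through every observation exactly and
is the simplest faithful reading of "fit spline curves through the
observed points".  Natural boundary conditions force zero curvature at
the window ends, so endpoint derivatives are the least reliable — first
and last timepoints are flagged in the derivative table, and an FMM
(not-a-knot style) boundary option is available; it reproduces
polynomials near the ends where the natural spline distorts.  For noisy
data a smoothing spline (`smoothing > 0`, passed as `spar`) replaces
interpolation; selection of the smoothing level is deliberately manual.
Derivatives are evaluated only at observation timepoints (matching the
one-factor-per-timepoint decomposition) and never outside the
observation window.  Both the squared (default) and absolute error-term
forms are supported; squared is the default for smoothness and
consistency with least-squares refinement, and the log floor (default
$10^{-12}$) guards the normalized log score against underflow.  The log
is natural; every property checked is invariant to the log base.

## Scoring

* **Weighted SSE** — the primal objective itself.
* **Species MRE** — $100 \times \max_{e,i,j} |x^{sim} - \hat x| /
  \max_j \hat x_{e,i,\cdot}$, range-normalized per species because
  pointwise normalization explodes near zero concentrations (the
  pointwise variant is available behind a flag).  Values above 100%
  mean the fit is unusable.  All-zero species are skipped with a warning.
* **PPE** — $100\,|\hat k_p - k_p|/k_p$ per parameter, aggregated by the
  **median**; it requires the true parameters and is therefore a
  simulation-only metric.

## The synthetic benchmark generator

The generator produces every input the test suite and the acceptance
script use:

* **Ring networks** — $n$ unimolecular conversions in a cycle, every ODE
  degree 2; the minimal scalable case.  The standard grid is 11
  timepoints on 0–4 s (0.4 s step), parameters on $[0.05, 1.05]$ in 10
  bins, nominal values snapped to bin midpoints when exact bin recovery
  is being tested.
* **Random low-degree networks** — two-thirds bimolecular
  ($A + B \to C$), one-third unimolecular conversions, species sampled
  proportionally to remaining degree capacity under a cap of 4, resampled
  until every species participates.  Default reaction count equals the
  species count, keeping mean degree between 2 and 3.
* **Akt topology** — a 16-species, 15-parameter reconstruction of
  serum-stimulated Akt activation with redox-regulated PTEN (serum →
  PI3K; serum → NOX-driven ROS production, antioxidant ROS decay,
  reversible ROS-mediated PTEN inactivation; PI3K/PTEN control of
  PIP2⇄PIP3; PIP3-dependent membrane recruitment of Akt and PDK1;
  membrane phosphorylation at Thr308; return to cytosol and PP2A
  dephosphorylation).  The **rate constants are synthetic unit-scale
  placeholders** (0.1–1), chosen once so all species show informative
  transients on the 0–4 s window; they are not literature kinetics, and
  any quantitative behaviour tied to the original calibrated model is
  reproduced in spirit only.  Supply `rates` to override.
* **Datasets** — simulated at nominal parameters from seeded random
  initial concentrations, uniform on $[0.1, 1]$ (fixable), one experiment
  by default; noise is multiplicative Gaussian,
  $\hat x = x(1 + \sigma z)$ clipped at zero, because percentage noise
  levels imply relative perturbations (an additive variant exists).  A
  scenario's seed fully determines its dataset, bit for bit.

What the generator emulates is dense, complete, synchronously sampled
concentration data with well-behaved relative noise.  What it does *not*
emulate: missing species or timepoints, non-mass-action kinetics,
heteroscedastic or correlated measurement error, and kinetic constants
spanning orders of magnitude.  Passing tests therefore demonstrate the
estimator's mechanics and its scaling behaviour, not performance on real
proteomic time courses.

## Problem sizes and known limitations

The packaged tests run rings up to 50 species (sweeps over 6–41
timepoints), random networks of 30 species, and the 16-species Akt
topology — sizes chosen so the full suite exercises every claim at
desk scale while the cell-count arithmetic, not wall-clock time, carries
the scaling argument.

Known limitations, all inherent to the method rather than the
implementation:

* Cost is exponential in network degree; a single high-degree hub makes
  the joint tables intractable.
* The product objective is an imperfect proxy for parameter accuracy:
  the MAP assignment occasionally scores better than the true parameters
  (and, on unlucky seeds, a near-tied bin can score slightly worse);
  refinement from the MAP midpoints absorbs these one-bin misses in the
  packaged benchmarks.
* At 20% observation noise the interpolated derivatives degrade enough
  that every method variant produces substantially worse fits than on
  clean data — the noise benchmark in the acceptance script quantifies
  this degradation rather than hiding it.
* Pure local search from a random start can land in poor local optima;
  the two-stage estimate is the supported workflow, and the random-start
  baseline is reported for comparison only.

## A worked miniature

```{r toy}
net <- parse_network(c("A -> B ; k1", "B -> A ; k2"))
traj <- simulate_network(net, c(0.45, 0.25), c(0.9, 0.1), seq(0, 4, 0.4))
fit <- spedre(net, traj)
summary(fit)
```

The MAP stage lands on the bins containing 0.45 and 0.25 (midpoints 0.5
and 0.3), and refinement returns the generating values to solver
precision.  `predict(fit)`, `residuals(fit)` and `plot(fit)` compare the
refitted trajectories against the observations.
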