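# spedre

Rate-parameter estimation for mass-action ODE models of biochemical
signalling networks in the *data-rich* regime — when every molecular
species has been measured densely in time (as modern proteomic time
courses increasingly allow). It is aimed at systems biologists who have
a reaction network with known topology, complete concentration time
series, and too many unknown rate constants for conventional
simulate-and-match searches to handle.

## Method

For a mass-action network, species $i$ obeys
$dx_i/dt = f_i(\bar x, \bar k) = \sum_{r \ni i} s_{ir}\, k_{p(r)}
\prod_{u \in \mathrm{react}(r)} x_u$. Instead of minimizing the primal
simulate-and-match objective
$\sum_{e,i,j} w_i (x_i(t_j;\bar k) - \hat x_{e,i,j})^2$ directly, the
estimator:

1. fits splines through the observed time courses and interpolates the
   derivatives $\widehat{dx_{e,i}/dt}(t_j)$;
2. forms one collocation error term per experiment, species and
   timepoint,
   $\varepsilon_{e,i,j}(\bar k) = (f_i(\hat x_e(t_j), \bar k) -
   \widehat{dx_{e,i}/dt}(t_j))^2$ — because $f_i$ is evaluated at the
   *observed* concentrations, each term involves only the few parameters
   in that species' ODE;
3. discretizes each parameter into equidistant bins, pre-computes a
   Boltzmann joint probability table
   $T_{e,i,j} \propto \exp(-\beta\,\varepsilon_{e,i,j})$ per term over
   the bins of its adjacent parameters, and runs max-product loopy
   belief propagation on the resulting factor graph to get a MAP bin
   assignment (cost $\sum_f \text{bins}^{\deg f}$: polynomial in
   species, timepoints and bins, exponential only in network degree);
4. refines the MAP midpoints by bounded Levenberg–Marquardt least
   squares on the primal objective.

Estimates are scored by weighted SSE, species maximum relative error
(MRE, range-normalized, in %) and parameter percentage error (PPE,
median-aggregated, in %). A synthetic benchmark generator (ring
networks, random low-degree networks, an Akt/PTEN signalling topology
with placeholder kinetics) makes the whole pipeline testable offline.
See `vignettes/spedre-methods.Rmd` for the full account.

## Worked example

```r
library(spedre)
net  <- parse_network(c("A -> B ; k1", "B -> A ; k2"))
traj <- simulate_network(net, c(0.45, 0.25), c(0.9, 0.1), seq(0, 4, 0.4))
fit  <- spedre(net, traj)     # 10 bins on [0.05, 1.05] by default
summary(fit)
```

```
Two-stage rate-parameter fit

 parameter map_bin midpoint refined belief
        k1       5      0.5    0.45 0.7863
        k2       3      0.3    0.25 0.7344

belief propagation: converged in 5 sweeps; 2,200 joint-table cells
refinement: weighted SSE 0.003843797 -> 1.322636e-26 in 4 iterations
```

Reading it: the discretized stage put `k1` in bin 5 (midpoint 0.5) and
`k2` in bin 3 (midpoint 0.3) — the bins containing the generating values
0.45 and 0.25 — evaluating 2,200 look-up-table cells (2 species × 11
timepoints × 10² bin pairs). Refinement then recovered the generating
values to solver precision, driving the weighted SSE from 3.8e-3 at the
midpoints to ~1e-26. `coef(fit)`, `predict(fit)`, `residuals(fit)`,
`plot(fit)` and `simulate(fit)` behave as for other fitted-model
objects.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli", "spedre", package = "spedre")`) with subcommands
`generate`, `simulate`, `estimate`, `score` and `benchmark`; models are
plain reaction-list text (`A + B -> C ; k3`) and data are one
`time,<species>,...` CSV per experiment.

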