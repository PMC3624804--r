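#' Fit rate parameters to dense time-series data
#'
#' The package's front door.  Runs the two-stage estimator on a
#' mass-action network and a data-rich dataset: (1) spline-interpolated
#' derivatives turn the problem into a product of low-dimensional
#' collocation error terms; the parameters are discretized into bins, each
#' error term becomes a pre-computed Boltzmann joint table, and max-product
#' loopy belief propagation returns a MAP bin assignment; (2) the bin
#' midpoints seed a bounded Levenberg-Marquardt refinement of the
#' simulate-and-match weighted SSE.  Set `refine = FALSE` to stop after
#' the discretized stage.
#'
#' @param network a [reaction_network()] (or reaction-list text /
#'   file path, passed to [parse_network()]).
#' @param data a [time_series_dataset()] (or a trajectory data frame /
#'   list of them).
#' @param bins bins per parameter (default 10).
#' @param lower,upper parameter domain bounds (default 0.05 and 1.05),
#'   scalars or per-parameter vectors.
#' @param smoothing,boundary spline options, see [fit_spline()].
#' @param beta Boltzmann scale, see [compute_joint_table()].
#' @param tol,max_iter propagation controls, see [run_lbp()].
#' @param damping,standard_bp propagation variants, see [run_lbp()].
#' @param form error-term form, see [error_term()].
#' @param refine run the refinement stage (default TRUE).
#' @param weights per-species weights for the refinement objective,
#'   see [weighted_sse()].
#' @param refine_max_iter refinement iteration cap.
#' @return An object of class `spedre` with components `coefficients`
#'   (refined rate constants, or MAP midpoints when `refine = FALSE`),
#'   `base` (the `map_result`), `refinement`, `scheme`, `network`, `data`,
#'   `cells` (joint-table cells evaluated), and `call`.  Supports `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot` and
#'   `simulate`.
#' @examples
#' net <- parse_network(c("A -> B ; k1", "B -> A ; k2"))
#' tr <- simulate_network(net, c(0.45, 0.25), c(0.9, 0.1), seq(0, 4, 0.4))
#' fit <- spedre(net, tr)
#' coef(fit)
#' @export
spedre <- function(network, data, bins = 10, lower = 0.05, upper = 1.05,
                   smoothing = 0, boundary = "natural", beta = NULL,
                   tol = 1e-6, max_iter = 100, damping = 0,
                   standard_bp = FALSE, form = "squared", refine = TRUE,
                   weights = NULL, refine_max_iter = 100) {
  cl <- match.call()
  if (is.character(network))
    network <- parse_network(network, file = length(network) == 1 &&
                               file.exists(network))
  if (!inherits(data, "spedre_data")) data <- time_series_dataset(data)
  data <- .align_dataset(network, data)
  scheme <- discretize_parameters(network, lower, upper, bins)
  derivs <- interpolated_derivatives(data, smoothing, boundary)
  base <- spedre_base(network, data, scheme, beta = beta, tol = tol,
                      max_iter = max_iter, damping = damping,
                      standard_bp = standard_bp, form = form,
                      derivs = derivs)
  refinement <- NULL
  par <- stats::setNames(base$estimate$midpoint, network$param_names)
  if (refine) {
    lo <- vapply(scheme, function(s) max(s$lower - s$width, 0), numeric(1))
    hi <- vapply(scheme, function(s) s$upper + s$width, numeric(1))
    # the logical argument `refine` does not shadow the function in a call
    refinement <- refine(network, base$estimate$midpoint, data,
                         lower = lo, upper = hi, weights = weights,
                         max_iter = refine_max_iter)
    par <- refinement$par
  }
  structure(list(coefficients = par, base = base, refinement = refinement,
                 scheme = scheme, network = network, data = data,
                 derivs = derivs, cells = base$cells, call = cl),
            class = "spedre")
}

#' @export
print.spedre <- function(x, ...) {
  cat("Two-stage rate-parameter fit (discretized MAP",
      if (!is.null(x$refinement)) "+ LM refinement" else "only", ")\n")
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 6))
  if (!x$base$converged)
    cat("\nNote: belief propagation hit the iteration cap (",
        x$base$iterations, " sweeps)\n", sep = "")
  invisible(x)
}

#' @export
coef.spedre <- function(object, ...) object$coefficients

#' @export
summary.spedre <- function(object, ...) {
  est <- object$base$estimate
  tab <- data.frame(parameter = est$param, map_bin = est$bin,
                    midpoint = est$midpoint,
                    refined = as.numeric(object$coefficients),
                    belief = vapply(object$base$beliefs, max, numeric(1)))
  structure(list(table = tab,
                 converged = object$base$converged,
                 iterations = object$base$iterations,
                 cells = object$cells,
                 refinement = object$refinement,
                 sse = if (!is.null(object$refinement))
                   object$refinement$sse
                 else weighted_sse(object$network, object$coefficients,
                                   object$data),
                 degenerate = object$base$degenerate),
            class = "summary.spedre")
}

#' @export
print.summary.spedre <- function(x, ...) {
  cat("Two-stage rate-parameter fit\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nbelief propagation:",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "sweeps;",
      format(x$cells, big.mark = ","), "joint-table cells\n")
  if (!is.null(x$refinement))
    cat("refinement: weighted SSE", format(x$refinement$sse_start),
        "->", format(x$refinement$sse), "in",
        x$refinement$iterations, "iterations\n")
  else cat("weighted SSE at MAP midpoints:", format(x$sse), "\n")
  if (length(x$degenerate))
    cat("near-uniform beliefs:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Predict trajectories from a fitted model
#'
#' Simulates the network at the fitted rate constants from an experiment's
#' observed initial condition.
#'
#' @param object a [spedre()] fit.
#' @param times timepoints (default the experiment's observation grid).
#' @param experiment experiment name or index (default first).
#' @param ... unused.
#' @return trajectory data frame (`time` column plus one per species).
#' @export
predict.spedre <- function(object, times = NULL, experiment = 1, ...) {
  e <- object$data$experiments[[experiment]]
  if (is.null(times)) times <- e$times
  simulate_network(object$network, object$coefficients,
                   pmax(e$obs[1, ], 0), times)
}

#' @export
fitted.spedre <- function(object, ...) {
  lapply(object$data$experiments, function(e) {
    sim <- simulate_network(object$network, object$coefficients,
                            pmax(e$obs[1, ], 0), e$times)
    as.matrix(sim[, object$data$species, drop = FALSE])
  })
}

#' @export
residuals.spedre <- function(object, ...) {
  fit <- fitted(object)
  lapply(names(object$data$experiments), function(nm) {
    object$data$experiments[[nm]]$obs - fit[[nm]]
  }) |> stats::setNames(names(object$data$experiments))
}

#' Plot observed points against fitted trajectories
#'
#' @param x a [spedre()] fit.
#' @param experiment experiment name or index.
#' @param species character vector of species to show (default all).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot.spedre <- function(x, experiment = 1, species = NULL, ...) {
  e <- x$data$experiments[[experiment]]
  if (is.null(species)) species <- x$data$species
  fine <- seq(min(e$times), max(e$times), length.out = 101)
  sim <- simulate_network(x$network, x$coefficients, pmax(e$obs[1, ], 0),
                          fine)
  cols <- grDevices::hcl.colors(length(species), "Dark 3")
  graphics::matplot(fine, as.matrix(sim[, species, drop = FALSE]),
                    type = "l", lty = 1, col = cols,
                    xlab = "time", ylab = "concentration", ...)
  graphics::matpoints(e$times, e$obs[, species, drop = FALSE],
                      pch = 1, col = cols)
  graphics::legend("topright", legend = species, col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Generates `nsim` datasets at the fitted rate constants, starting from
#' each experiment's observed initial condition, with optional
#' multiplicative noise — useful for parametric-bootstrap style checks.
#'
#' @param object a [spedre()] fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param noise relative noise level (fraction).
#' @param ... unused.
#' @return list of `nsim` [time_series_dataset()] objects.
#' @export
simulate.spedre <- function(object, nsim = 1, seed = 1, noise = 0, ...) {
  e1 <- object$data$experiments[[1]]
  lapply(seq_len(nsim), function(r) {
    sc <- benchmark_scenario(object$network, object$coefficients,
                             times = e1$times, noise = noise,
                             seed = seed + r - 1,
                             initial = pmax(e1$obs[1, ], 0))
    generate_dataset(sc)
  })
}
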