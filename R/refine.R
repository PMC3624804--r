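#' Default per-species weights for the simulate-and-match objective
#'
#' `w_i = 1 / max(obs_i)^2`, with the maximum taken over all experiments
#' and timepoints, so species on different concentration scales contribute
#' comparably.  An all-zero species gets weight 1.
#'
#' @param dataset a [time_series_dataset()].
#' @return named numeric vector, one weight per species.
#' @export
default_weights <- function(dataset) {
  mx <- apply(do.call(rbind, lapply(dataset$experiments, `[[`, "obs")),
              2, max)
  w <- ifelse(mx > 0, 1 / mx^2, 1)
  stats::setNames(w, dataset$species)
}

# residual vector sqrt(w_i) * (x_sim - x_obs) over all (e, i, j);
# integrator failure yields a large finite penalty so optimizers recover.
.primal_residuals <- function(network, params, dataset, weights,
                              penalty = 1e6) {
  sw <- sqrt(weights)
  unlist(lapply(dataset$experiments, function(e) {
    sim <- tryCatch(
      simulate_network(network, params, pmax(e$obs[1, ], 0), e$times),
      error = function(err) NULL)
    if (is.null(sim)) return(rep(penalty, length(e$obs)))
    R <- (as.matrix(sim[, dataset$species, drop = FALSE]) - e$obs)
    as.vector(sweep(R, 2, sw, "*"))
  }), use.names = FALSE)
}

#' Weighted sum-of-squares simulate-and-match objective
#'
#' The primal objective: simulate the network from each experiment's
#' observed initial condition and sum the weighted squared deviations from
#' the observations over all experiments, species and timepoints.
#'
#' @param network a [reaction_network()].
#' @param params rate-parameter vector.
#' @param dataset a [time_series_dataset()].
#' @param weights positive per-species weights; default [default_weights()].
#' @return non-negative scalar (a large finite penalty if integration
#'   fails at `params`).
#' @export
weighted_sse <- function(network, params, dataset, weights = NULL) {
  dataset <- .align_dataset(network, dataset)
  if (is.null(weights)) weights <- default_weights(dataset)
  stopifnot(all(weights > 0), length(weights) == length(dataset$species))
  sum(.primal_residuals(network, params, dataset, weights)^2)
}

#' Local refinement by bounded Levenberg-Marquardt least squares
#'
#' Minimizes the weighted simulate-and-match residual vector starting from
#' `start` (typically MAP bin midpoints), using `minpack.lm::nls.lm` with a
#' finite-difference Jacobian and box bounds.  The refined objective value
#' never exceeds the starting one: if the solver fails to improve, the
#' start vector is returned.
#'
#' @inheritParams weighted_sse
#' @param start starting parameter vector (within bounds).
#' @param lower,upper per-parameter box bounds (recycled).
#' @param max_iter solver iteration cap.
#' @return An object of class `spedre_refinement`: `par` (refined vector),
#'   `start`, `sse_start`, `sse`, `iterations`, `converged`, `message`.
#' @export
refine <- function(network, start, dataset, lower = 0, upper = Inf,
                   weights = NULL, max_iter = 100) {
  dataset <- .align_dataset(network, dataset)
  if (is.null(weights)) weights <- default_weights(dataset)
  p <- n_parameters(network)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  stopifnot(length(start) == p, all(start >= lower), all(start <= upper))
  fn <- function(par) .primal_residuals(network, par, dataset, weights)
  sse0 <- sum(fn(start)^2)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter)),
    error = function(err) NULL)
  if (is.null(fit)) {
    par <- start; sse1 <- sse0; iters <- 0L
    conv <- FALSE; msg <- "solver error; start returned"
  } else {
    par <- as.numeric(fit$par)
    sse1 <- sum(fn(par)^2)
    iters <- fit$niter
    conv <- fit$info %in% 1:4
    msg <- fit$message
    if (sse1 > sse0) {  # guard the monotone-improvement invariant
      par <- start; sse1 <- sse0
      msg <- paste(msg, "(no improvement; start returned)")
    }
  }
  structure(list(par = stats::setNames(par, network$param_names),
                 start = stats::setNames(start, network$param_names),
                 sse_start = sse0, sse = sse1, iterations = iters,
                 converged = conv, message = msg),
            class = "spedre_refinement")
}

#' @export
print.spedre_refinement <- function(x, ...) {
  cat("Levenberg-Marquardt refinement:",
      if (x$converged) "converged" else "not converged",
      "in", x$iterations, "iterations\n")
  cat("  weighted SSE:", format(x$sse_start), "->", format(x$sse), "\n")
  print(round(rbind(start = x$start, refined = x$par), 6))
  invisible(x)
}

#' Full two-stage estimation (base stage plus refinement)
#'
#' Runs [spedre_base()] and refines the MAP bin midpoints with [refine()].
#' Refinement bounds default to the discretization bounds expanded by one
#' bin width on each side (floored at 0).  Deterministic given its inputs.
#'
#' @inheritParams spedre_base
#' @param weights see [weighted_sse()].
#' @param refine_max_iter iteration cap for the refinement stage.
#' @return list with `$base` (a `map_result`), `$refinement`
#'   (a `spedre_refinement`), and `$par` (the refined parameter vector).
#' @export
spedre_full <- function(network, dataset, scheme = NULL, beta = NULL,
                        tol = 1e-6, max_iter = 100, smoothing = 0,
                        boundary = "natural", damping = 0,
                        standard_bp = FALSE, form = "squared",
                        weights = NULL, refine_max_iter = 100) {
  if (is.null(scheme)) scheme <- discretize_parameters(network)
  dataset <- .align_dataset(network, dataset)
  base <- spedre_base(network, dataset, scheme, beta = beta, tol = tol,
                      max_iter = max_iter, smoothing = smoothing,
                      boundary = boundary, damping = damping,
                      standard_bp = standard_bp, form = form)
  lo <- vapply(scheme, function(s) max(s$lower - s$width, 0), numeric(1))
  hi <- vapply(scheme, function(s) s$upper + s$width, numeric(1))
  ref <- refine(network, base$estimate$midpoint, dataset,
                lower = lo, upper = hi, weights = weights,
                max_iter = refine_max_iter)
  list(base = base, refinement = ref, par = ref$par)
}
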