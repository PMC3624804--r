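#' Collocation error terms and the product-of-functions objective
#'
#' For every (experiment `e`, species `i`, timepoint `j`) the error term is
#' the squared discrepancy between the ODE right-hand side evaluated at the
#' *observed* concentrations and the derivative interpolated from the data:
#' \deqn{\varepsilon_{e,i,j} = \big(f_i(\hat x_e(t_j), k) - d\hat
#' x_{e,i}/dt|_{t_j}\big)^2.}
#' Evaluating \eqn{f_i} at observed rather than simulated concentrations is
#' what decouples the terms: each depends only on the few parameters
#' appearing in species `i`'s ODE.  When the derivative table was built
#' with `smoothing > 0`, the spline-smoothed concentrations are used in
#' place of the raw observations, consistently with the derivatives.
#'
#' @param network a [reaction_network()].
#' @param params full-length rate-parameter vector.
#' @param dataset a [time_series_dataset()].
#' @param derivs a `deriv_table` from [interpolated_derivatives()].
#' @param experiment experiment name or index.
#' @param species species name or index.
#' @param timepoint timepoint index (within the experiment).
#' @param form `"squared"` (default) or `"absolute"` discrepancy.
#' @return non-negative scalar.
#' @export
error_term <- function(network, params, dataset, derivs,
                       experiment, species, timepoint, form = "squared") {
  e <- .exp_name(dataset, experiment)
  i <- if (is.character(species)) match(species, dataset$species) else species
  stopifnot(!is.na(i), i >= 1, i <= length(dataset$species))
  D <- derivs$deriv[[e]]
  if (is.null(D) || timepoint < 1 || timepoint > nrow(D))
    stop("missing derivative entry for (", e, ", ", species, ", ",
         timepoint, ")")
  state <- derivs$smooth[[e]][timepoint, ]
  f <- ode_rhs(network, params, state)[i]
  r <- f - D[timepoint, i]
  if (match.arg(form, c("squared", "absolute")) == "squared") r^2 else abs(r)
}

.exp_name <- function(dataset, experiment) {
  if (is.character(experiment)) {
    if (!experiment %in% names(dataset$experiments))
      stop("unknown experiment '", experiment, "'")
    experiment
  } else names(dataset$experiments)[experiment]
}

# All error terms at once; returns per-experiment matrices (timepoints x
# species).  The mass-action RHS at fixed concentrations is linear in the
# parameters, so this is a single matrix product per experiment.
.all_epsilons <- function(network, params, dataset, derivs,
                          form = "squared") {
  S <- network$stoich
  lapply(stats::setNames(nm = names(dataset$experiments)), function(nm) {
    X <- derivs$smooth[[nm]]
    rates <- sapply(network$reactions, function(rx) {
      v <- params[rx$param] * X[, rx$reactants[1]]
      if (length(rx$reactants) == 2) v <- v * X[, rx$reactants[2]]
      v
    })
    if (is.null(dim(rates))) rates <- matrix(rates, nrow = nrow(X))
    F <- rates %*% t(S)
    R <- F - derivs$deriv[[nm]]
    if (form == "squared") R^2 else abs(R)
  })
}

#' Product-of-functions objective
#'
#' The product over all (experiment, species, timepoint) of the error terms.
#' The product is decomposable — it is minimized when every individual term
#' is minimized — but numerically hazardous: it collapses to zero if any
#' single term is zero, and underflows for many small terms.  Use
#' [normalized_log_pof()] for a stable score.
#'
#' @inheritParams error_term
#' @return non-negative scalar (possibly 0 or underflowed).
#' @export
pof <- function(network, params, dataset, derivs, form = "squared") {
  prod(unlist(.all_epsilons(network, params, dataset, derivs, form)))
}

#' Normalized log product-of-functions
#'
#' The mean, over all error terms, of `log(max(eps, floor))`: the log of the
#' product-of-functions objective normalized by the number of factors.
#' Lower is better.  The floor guards against terms that underflow to zero.
#'
#' @inheritParams error_term
#' @param floor positive lower clamp applied inside the log (default 1e-12).
#' @return scalar (natural log scale).
#' @export
normalized_log_pof <- function(network, params, dataset, derivs,
                               floor = 1e-12, form = "squared") {
  stopifnot(floor > 0)
  eps <- unlist(.all_epsilons(network, params, dataset, derivs, form))
  mean(log(pmax(eps, floor)))
}

#' Dump all error terms as a long data frame
#'
#' Diagnostic view of the decomposed objective at one parameter vector.
#'
#' @inheritParams error_term
#' @return data frame with columns `experiment`, `species`, `time`,
#'   `epsilon`, `is_boundary`.
#' @export
error_term_table <- function(network, params, dataset, derivs,
                             form = "squared") {
  eps <- .all_epsilons(network, params, dataset, derivs, form)
  do.call(rbind, lapply(names(eps), function(nm) {
    E <- eps[[nm]]
    data.frame(
      experiment = nm,
      species = rep(dataset$species, each = nrow(E)),
      time = rep(dataset$experiments[[nm]]$times, times = ncol(E)),
      epsilon = as.vector(E),
      is_boundary = rep(derivs$is_boundary[[nm]], times = ncol(E)))
  }))
}

# Affine representation of one error term: at fixed observed concentrations
# the RHS of species i is sum_p a_p * k_p, so eps(k) = (sum a_p k_p - d)^2.
# Returns coefficients over params_in_ode(i) plus the derivative target.
.error_affine <- function(network, dataset, derivs, experiment, species_idx,
                          timepoint) {
  e <- .exp_name(dataset, experiment)
  state <- derivs$smooth[[e]][timepoint, ]
  pidx <- params_in_ode(network, species_idx)
  a <- stats::setNames(numeric(length(pidx)), network$param_names[pidx])
  for (rx in network$reactions) {
    sgn <- sum(rx$products == species_idx) - sum(rx$reactants == species_idx)
    if (sgn == 0 && !species_idx %in% c(rx$reactants, rx$products)) next
    pos <- match(rx$param, pidx)
    if (!is.na(pos)) a[pos] <- a[pos] + sgn * prod(state[rx$reactants])
  }
  list(params = pidx, coef = a,
       target = derivs$deriv[[e]][timepoint, species_idx])
}
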