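#' Equidistant parameter bins
#'
#' Discretizes one parameter's domain into `count` equidistant bins, each
#' represented by its midpoint: `m_b = lower + (b - 0.5) * width` with
#' `width = (upper - lower) / count` (bins are 1-based).
#'
#' @param lower,upper domain bounds, `upper > lower`.
#' @param count number of bins (>= 1; a single bin is degenerate and
#'   triggers a warning).
#' @return An object of class `bin_scheme` with fields `lower`, `upper`,
#'   `count`, `width`, `midpoints`.
#' @examples
#' build_bins(0.05, 1.05, 10)$midpoints  # 0.1, 0.2, ..., 1.0
#' @export
build_bins <- function(lower, upper, count) {
  stopifnot(is.numeric(lower), is.numeric(upper), count >= 1)
  if (upper <= lower) stop("non-positive bin width: upper must exceed lower")
  count <- as.integer(count)
  if (count == 1L)
    warning("a single bin cannot discriminate parameter values")
  width <- (upper - lower) / count
  structure(list(lower = lower, upper = upper, count = count,
                 width = width,
                 midpoints = lower + (seq_len(count) - 0.5) * width),
            class = "bin_scheme")
}

#' Discretization scheme for all parameters of a network
#'
#' @param network a [reaction_network()].
#' @param lower,upper,bins scalars (recycled) or per-parameter vectors.
#' @return An object of class `discretization`: a named list of
#'   [build_bins()] schemes, one per parameter.
#' @export
discretize_parameters <- function(network, lower = 0.05, upper = 1.05,
                                  bins = 10) {
  p <- n_parameters(network)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  bins <- rep_len(bins, p)
  out <- lapply(seq_len(p), function(k) build_bins(lower[k], upper[k], bins[k]))
  names(out) <- network$param_names
  structure(out, class = "discretization")
}

#' Midpoints of a bin assignment
#' @param scheme a [discretize_parameters()] scheme.
#' @param bins integer vector of bin indices (1-based), one per parameter.
#' @return numeric vector of midpoint values.
#' @export
midpoints_of <- function(scheme, bins) {
  stopifnot(length(bins) == length(scheme))
  vapply(seq_along(scheme), function(k) scheme[[k]]$midpoints[bins[k]],
         numeric(1))
}

#' Snap parameter values to the nearest bin midpoints
#' @param params numeric parameter vector.
#' @param scheme a [discretize_parameters()] scheme.
#' @return numeric vector of the nearest midpoints.
#' @export
snap_to_midpoints <- function(params, scheme) {
  stopifnot(length(params) == length(scheme))
  vapply(seq_along(scheme), function(k) {
    m <- scheme[[k]]$midpoints
    m[which.min(abs(m - params[k]))]
  }, numeric(1))
}

#' Build the factor-graph structure for a network and dataset
#'
#' The factor graph is bipartite: one variable node per unknown rate
#' parameter and one factor node per (experiment, species, timepoint) error
#' term.  A factor is adjacent to a parameter iff the parameter appears in
#' that species' ODE.  Factors are ordered lexicographically by
#' (experiment, species, timepoint), which also fixes the message schedule.
#'
#' @param network a [reaction_network()].
#' @param dataset a [time_series_dataset()].
#' @return An object of class `factor_graph` with `$factors` (each holding
#'   `experiment`, `species`, `timepoint`, `vars`) and `$n_params`.
#' @export
build_factor_graph <- function(network, dataset) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(dataset, "spedre_data"))
  dataset <- .align_dataset(network, dataset)
  adj <- lapply(seq_along(network$species),
                function(i) params_in_ode(network, i))
  covered <- sort(unique(unlist(adj)))
  missing <- setdiff(seq_len(n_parameters(network)), covered)
  if (length(missing))
    stop("parameter(s) appearing in no ODE (unidentifiable): ",
         paste(network$param_names[missing], collapse = ", "))
  factors <- list()
  for (e in names(dataset$experiments)) {
    nt <- length(dataset$experiments[[e]]$times)
    for (i in seq_along(network$species)) {
      if (length(adj[[i]]) == 0) next  # isolated species: no factors
      for (j in seq_len(nt)) {
        factors[[length(factors) + 1L]] <- list(
          experiment = e, species = i,
          species_name = network$species[i],
          timepoint = j, vars = adj[[i]])
      }
    }
  }
  structure(list(factors = factors, n_params = n_parameters(network),
                 param_names = network$param_names),
            class = "factor_graph")
}

#' @export
print.factor_graph <- function(x, ...) {
  degs <- vapply(x$factors, function(f) length(f$vars), 1L)
  cat("Factor graph:", length(x$factors), "factor nodes,",
      x$n_params, "variable nodes, max factor degree", max(degs), "\n")
  invisible(x)
}

#' Joint probability look-up table for one factor
#'
#' Evaluates the factor's error term at every combination of bin midpoints
#' of its adjacent parameters and converts the errors to probabilities by
#' Boltzmann weighting, `p(cell) = C * exp(-beta * eps(cell))`, with `C`
#' normalizing the table to sum 1.  Normalization happens in log space with
#' max-subtraction, so an all-tiny table never collapses to zero.
#'
#' @param factor one element of `build_factor_graph()$factors`.
#' @param network,dataset,derivs as in [error_term()].
#' @param scheme a [discretize_parameters()] scheme.
#' @param beta positive Boltzmann scale, or `NULL` (default) for the
#'   per-factor adaptive scale `1 / max(median(eps), 1e-12)`, which keeps
#'   tables neither flat nor one-hot across problem scales.
#' @param form error-term form, see [error_term()].
#' @return An object of class `joint_table`: `vars` (parameter indices),
#'   `prob` (d-dimensional array summing to 1), `log_prob`, `beta`, `cells`.
#' @export
compute_joint_table <- function(factor, network, dataset, derivs, scheme,
                                beta = NULL, form = "squared") {
  aff <- .error_affine(network, dataset, derivs, factor$experiment,
                       factor$species, factor$timepoint)
  stopifnot(identical(aff$params, factor$vars))
  d <- length(factor$vars)
  terms <- lapply(seq_len(d), function(q)
    aff$coef[q] * scheme[[factor$vars[q]]]$midpoints)
  lin <- if (d == 1L) terms[[1]] else
    Reduce(function(acc, v) outer(acc, v, "+"), terms[-1], terms[[1]])
  eps <- (lin - aff$target)
  eps <- if (match.arg(form, c("squared", "absolute")) == "squared")
    eps^2 else abs(eps)
  dims <- vapply(factor$vars, function(p) scheme[[p]]$count, 1L)
  eps <- array(eps, dim = dims)
  if (is.null(beta)) beta <- 1 / max(stats::median(eps), 1e-12)
  stopifnot(beta > 0)
  lw <- -beta * eps
  lw <- lw - max(lw)
  prob <- exp(lw) / sum(exp(lw))
  structure(list(vars = factor$vars, prob = prob,
                 log_prob = log(prob), beta = beta,
                 cells = prod(dims)), class = "joint_table")
}

#' Lexicographically-first maximizing cell of a joint table
#'
#' @param table a [compute_joint_table()] result (or any non-negative
#'   array wrapped in `list(prob = ...)`).
#' @return integer vector of bin indices (1-based), one per dimension;
#'   among ties, the lexicographically smallest index vector.
#' @export
table_argmax <- function(table) {
  arr <- if (is.list(table)) table$prob else table
  mx <- max(arr)
  cand <- arrayInd(which(arr == mx), .dim_of(arr))
  cand <- cand[do.call(order, as.data.frame(cand)), , drop = FALSE]
  as.integer(cand[1, ])
}

.dim_of <- function(arr) if (is.null(dim(arr))) length(arr) else dim(arr)

#' Max-marginalization of an array over all but one dimension
#'
#' `out[b] = max over all other dimensions of g` with the kept dimension
#' fixed at `b` — the maximization operator used by the max-product message
#' updates.
#'
#' @param g a numeric array (a 1-D vector is returned unchanged).
#' @param keep_dim dimension index to keep.
#' @return numeric vector of length `dim(g)[keep_dim]`.
#' @export
max_marginalize <- function(g, keep_dim) {
  d <- .dim_of(g)
  stopifnot(keep_dim >= 1, keep_dim <= length(d))
  if (length(d) == 1L) return(as.numeric(g))
  as.numeric(apply(g, keep_dim, max))
}

# add a per-bin vector to an array along one dimension
.add_along <- function(arr, vec, dim) {
  if (length(.dim_of(arr)) == 1L) return(arr + vec)
  sweep(arr, dim, vec, "+")
}

#' Run max-product loopy belief propagation
#'
#' Implements the message-passing variant in which a variable node's
#' message to a factor is its *current full belief* (not the textbook
#' exclusion of the recipient factor's own contribution; set
#' `standard_bp = TRUE` for the textbook rule).  Each sweep processes the
#' factors in their fixed lexicographic order: for each factor and each
#' adjacent variable the factor-to-variable message is the
#' max-marginalization, over the other dimensions, of the log joint table
#' plus the incoming log beliefs; messages are normalized and stored in the
#' variable's message history.  After the factor sweep every variable's
#' belief becomes the normalized product of its stored incoming messages.
#' All bookkeeping is in log space with max-subtraction at normalization
#' points.  Convergence is declared when no normalized message changes by
#' more than `tol` (sup norm) between sweeps; hitting `max_iter` flags
#' non-convergence but is not an error, since loopy propagation may
#' oscillate on cyclic graphs.
#'
#' @param graph a [build_factor_graph()] result whose factors carry joint
#'   tables (see [spedre_base()] for the composed pipeline); alternatively
#'   pass `tables` explicitly.
#' @param tables list of [compute_joint_table()] results, parallel to
#'   `graph$factors`.
#' @param scheme the [discretize_parameters()] scheme.
#' @param tol convergence tolerance on messages (default 1e-6).
#' @param max_iter sweep cap (default 100).
#' @param damping message damping in `[0, 1)`; 0 (default) = none.
#' @param standard_bp use the textbook variable-to-factor exclusion rule.
#' @return An object of class `map_result`: data frame `$estimate` with
#'   columns `param`, `bin`, `midpoint`; `$beliefs` (list of final belief
#'   vectors); `$converged`; `$iterations`; `$message_trace` (per-sweep max
#'   message change); `$degenerate` (parameters with near-uniform beliefs).
#' @export
run_lbp <- function(graph, tables, scheme, tol = 1e-6, max_iter = 100,
                    damping = 0, standard_bp = FALSE) {
  stopifnot(inherits(graph, "factor_graph"),
            length(tables) == length(graph$factors),
            damping >= 0, damping < 1, max_iter >= 1)
  if (length(graph$factors) == 0) stop("empty factor graph")
  P <- graph$n_params
  nb <- vapply(seq_len(P), function(p) scheme[[p]]$count, 1L)
  log_belief <- lapply(nb, function(B) rep(-log(B), B))
  # message history: per parameter, rows = factors adjacent to it
  fac_of <- lapply(seq_len(P), function(p)
    which(vapply(graph$factors, function(f) p %in% f$vars, logical(1))))
  hist_log <- lapply(seq_len(P), function(p)
    matrix(-log(nb[p]), nrow = length(fac_of[[p]]), ncol = nb[p]))
  hist_prob <- lapply(hist_log, exp)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    maxdiff <- 0
    for (fi in seq_along(graph$factors)) {
      f <- graph$factors[[fi]]
      Tlog <- tables[[fi]]$log_prob
      for (q in seq_along(f$vars)) {
        K <- f$vars[q]
        g <- Tlog
        for (q2 in seq_along(f$vars)) {
          if (q2 == q) next
          K2 <- f$vars[q2]
          inc <- if (standard_bp) {
            row <- match(fi, fac_of[[K2]])
            .normalize_log(colSums(hist_log[[K2]]) - hist_log[[K2]][row, ])
          } else log_belief[[K2]]
          g <- .add_along(g, inc, q2)
        }
        msg <- max_marginalize(g, q)
        msg_p <- .normalize_log_to_prob(msg)
        row <- match(fi, fac_of[[K]])
        if (damping > 0)
          msg_p <- .renorm((1 - damping) * msg_p +
                           damping * hist_prob[[K]][row, ])
        maxdiff <- max(maxdiff, max(abs(msg_p - hist_prob[[K]][row, ])))
        hist_prob[[K]][row, ] <- msg_p
        hist_log[[K]][row, ] <- log(pmax(msg_p, .Machine$double.xmin))
      }
    }
    for (p in seq_len(P))
      log_belief[[p]] <- .normalize_log(colSums(hist_log[[p]]))
    trace <- c(trace, maxdiff)
    if (maxdiff <= tol) { converged <- TRUE; break }
  }
  beliefs <- lapply(log_belief, .normalize_log_to_prob)
  names(beliefs) <- graph$param_names
  bins <- vapply(beliefs, function(b) which.max(b), 1L)
  degen <- graph$param_names[vapply(beliefs, function(b)
    max(b) - min(b) < 1e-8, logical(1))]
  est <- data.frame(param = graph$param_names, bin = as.integer(bins),
                    midpoint = midpoints_of(scheme, bins))
  structure(list(estimate = est, beliefs = beliefs, converged = converged,
                 iterations = it, message_trace = trace,
                 degenerate = degen), class = "map_result")
}

.normalize_log <- function(lx) {
  m <- max(lx)
  lx - m - log(sum(exp(lx - m)))
}

.normalize_log_to_prob <- function(lx) {
  p <- exp(lx - max(lx))
  p / sum(p)
}

.renorm <- function(p) p / sum(p)

#' @export
print.map_result <- function(x, ...) {
  cat("MAP bin assignment (",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " sweeps)\n", sep = "")
  print(x$estimate, row.names = FALSE)
  if (length(x$degenerate))
    cat("near-uniform beliefs (possibly non-identifiable):",
        paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' Discretized factor-graph estimation (base stage)
#'
#' Composes the pipeline: spline-interpolated derivatives, factor-graph
#' construction, joint-table pre-computation (the tables never change
#' during propagation), and max-product loopy belief propagation.  Returns
#' the MAP bin assignment; the result is deterministic given its inputs.
#'
#' @inheritParams run_lbp
#' @param network a [reaction_network()].
#' @param dataset a [time_series_dataset()].
#' @param scheme a [discretize_parameters()] scheme (defaults to 10 bins on
#'   `[0.05, 1.05]` per parameter).
#' @param beta Boltzmann scale, see [compute_joint_table()].
#' @param smoothing,boundary spline options, see
#'   [interpolated_derivatives()].
#' @param form error-term form, see [error_term()].
#' @param derivs optional pre-computed derivative table.
#' @return A `map_result` (see [run_lbp()]) with an added `$cells` field:
#'   the total number of joint-table cells evaluated, exactly
#'   `sum(bins^degree)` over factors.
#' @export
spedre_base <- function(network, dataset, scheme = NULL, beta = NULL,
                        tol = 1e-6, max_iter = 100, smoothing = 0,
                        boundary = "natural", damping = 0,
                        standard_bp = FALSE, form = "squared",
                        derivs = NULL) {
  if (is.null(scheme)) scheme <- discretize_parameters(network)
  dataset <- .align_dataset(network, dataset)
  if (is.null(derivs))
    derivs <- interpolated_derivatives(dataset, smoothing, boundary)
  graph <- build_factor_graph(network, dataset)
  tables <- lapply(graph$factors, compute_joint_table, network = network,
                   dataset = dataset, derivs = derivs, scheme = scheme,
                   beta = beta, form = form)
  res <- run_lbp(graph, tables, scheme, tol = tol, max_iter = max_iter,
                 damping = damping, standard_bp = standard_bp)
  res$cells <- sum(vapply(tables, function(tt) tt$cells, numeric(1)))
  if (length(res$degenerate))
    warning("near-uniform belief for ",
            paste(res$degenerate, collapse = ", "),
            "; parameter(s) may be non-identifiable from these data")
  res
}
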