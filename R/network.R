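#' Mass-action reaction networks
#'
#' A `reaction_network` holds an ordered species list, a list of mass-action
#' reactions (each with at most two reactants and two products and exactly one
#' rate parameter), and the parameter names.  The right-hand side of the ODE
#' for species \eqn{i} is the signed sum, over reactions touching \eqn{i}, of
#' the mass-action rate \eqn{k \prod_r x_r}: negative for reactants, positive
#' for products.  A species appearing on both sides of a reaction (a catalyst)
#' contributes a net-zero term but still counts towards the ODE degree and the
#' factor-graph adjacency.
#'
#' @param species character vector of species names (order defines indices).
#' @param reactions list of reactions, each a list with integer fields
#'   `reactants` (length 1-2), `products` (length 0-2) and `param`
#'   (1-based index into `param_names`).
#' @param param_names character vector of rate-parameter names.
#' @return An object of class `reaction_network`.
#' @seealso [parse_network()], [ode_rhs()], [simulate_network()]
#' @export
reaction_network <- function(species, reactions, param_names) {
  stopifnot(is.character(species), length(species) >= 1,
            !anyDuplicated(species), is.list(reactions),
            length(reactions) >= 1, is.character(param_names))
  n_s <- length(species)
  n_p <- length(param_names)
  for (rx in reactions) {
    if (!length(rx$reactants) %in% 1:2)
      stop("each reaction needs 1 or 2 reactants")
    if (length(rx$products) > 2)
      stop("at most 2 products per reaction")
    idx <- c(rx$reactants, rx$products)
    if (any(idx < 1L | idx > n_s)) stop("species index out of range")
    if (length(rx$param) != 1L || rx$param < 1L || rx$param > n_p)
      stop("each reaction needs exactly one valid rate parameter")
  }
  used <- sort(unique(vapply(reactions, function(r) as.integer(r$param), 1L)))
  if (!identical(used, seq_len(n_p)))
    stop("every rate parameter must be used by at least one reaction")
  net <- structure(list(species = species, reactions = reactions,
                        param_names = param_names),
                   class = "reaction_network")
  net$stoich <- .stoich_matrix(net)
  net
}

# signed stoichiometry: n_species x n_reactions, entries in {-2,...,2}
.stoich_matrix <- function(net) {
  S <- matrix(0, length(net$species), length(net$reactions))
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    for (i in rx$reactants) S[i, j] <- S[i, j] - 1
    for (i in rx$products)  S[i, j] <- S[i, j] + 1
  }
  S
}

#' Number of species / parameters / reactions
#' @param network a [reaction_network()].
#' @return integer count.
#' @export
n_species <- function(network) length(network$species)

#' @rdname n_species
#' @export
n_parameters <- function(network) length(network$param_names)

#' @rdname n_species
#' @export
n_reactions <- function(network) length(network$reactions)

#' Parse a reaction-list model
#'
#' Line format: `<reactants> -> <products> ; <param>` with `+`-separated
#' species, e.g. `A + B -> C ; k3`.  `#` starts a comment; blank lines are
#' ignored.  Species are registered in order of first appearance (reactants
#' before products, line by line).  An empty product side (`A -> ; kdeg` or
#' `A -> 0 ; kdeg`) denotes degradation.  Re-using a parameter name on several
#' lines shares that parameter.
#'
#' @param text character scalar or vector of lines, or a file path when
#'   `file = TRUE`.
#' @param file if `TRUE`, `text` names a file to read.
#' @return A [reaction_network()].
#' @examples
#' net <- parse_network(c("A -> B ; k1", "B -> A ; k2"))
#' net
#' @export
parse_network <- function(text, file = FALSE) {
  if (file) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no reactions in model text")
  species <- character()
  params <- character()
  reactions <- list()
  reg <- function(name) {
    if (!name %in% species) species <<- c(species, name)
    match(name, species)
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^(.*?)->(.*?);(.*)$", ln))[[1]]
    if (length(m) != 4)
      stop("malformed reaction line: '", ln, "'")
    side <- function(s) {
      s <- trimws(s)
      if (!nzchar(s) || s == "0") return(character())
      parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      n_plus <- nchar(gsub("[^+]", "", s))
      if (length(parts) != n_plus + 1L || any(!nzchar(parts)) ||
          any(grepl("[;>[:space:]]", parts)))
        stop("malformed species list in line: '", ln, "'")
      parts
    }
    lhs <- side(m[2]); rhs <- side(m[3]); pname <- trimws(m[4])
    if (length(lhs) == 0) stop("reaction needs at least one reactant: '", ln, "'")
    if (length(lhs) > 2) stop("at most 2 reactants supported: '", ln, "'")
    if (length(rhs) > 2) stop("at most 2 products supported: '", ln, "'")
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", pname))
      stop("malformed parameter name in line: '", ln, "'")
    r_idx <- vapply(lhs, reg, 1L)
    p_idx <- vapply(rhs, reg, 1L)
    if (!pname %in% params) params <- c(params, pname)
    reactions[[length(reactions) + 1L]] <-
      list(reactants = as.integer(r_idx), products = as.integer(p_idx),
           param = match(pname, params))
  }
  reaction_network(species, reactions, params)
}

#' Serialize a network back to reaction-list text
#' @param network a [reaction_network()].
#' @return character vector, one line per reaction.
#' @export
format_network <- function(network) {
  vapply(network$reactions, function(rx) {
    lhs <- paste(network$species[rx$reactants], collapse = " + ")
    rhs <- if (length(rx$products)) {
      paste(network$species[rx$products], collapse = " + ")
    } else "0"
    paste0(lhs, " -> ", rhs, " ; ", network$param_names[rx$param])
  }, character(1))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Mass-action reaction network\n")
  cat("  species:   ", length(x$species), "\n")
  cat("  reactions: ", length(x$reactions), "\n")
  cat("  parameters:", length(x$param_names), "\n")
  cat("  max ODE degree:", network_degree(x), "\n")
  lines <- format_network(x)
  show <- utils::head(lines, 10L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(lines) > 10L) cat("  ... (", length(lines) - 10L, " more)\n")
  invisible(x)
}

#' Evaluate the ODE right-hand side
#'
#' @param network a [reaction_network()].
#' @param params numeric rate-parameter vector, length `n_parameters(network)`.
#' @param state numeric concentration vector, length `n_species(network)`.
#' @return numeric derivative vector, one entry per species.
#' @examples
#' net <- parse_network(c("A -> B ; k1", "B -> A ; k2"))
#' ode_rhs(net, c(0.3, 0.1), c(1, 1))  # -0.2, 0.2
#' @export
ode_rhs <- function(network, params, state) {
  if (length(params) != n_parameters(network))
    stop("params has length ", length(params), ", expected ",
         n_parameters(network))
  if (length(state) != n_species(network))
    stop("state has length ", length(state), ", expected ",
         n_species(network))
  as.numeric(network$stoich %*% .reaction_rates(network, params, state))
}

.reaction_rates <- function(network, params, state) {
  vapply(network$reactions, function(rx) {
    params[rx$param] * prod(state[rx$reactants])
  }, numeric(1))
}

#' ODE degree of a species
#'
#' The degree of a species' ODE is the number of terms on its right-hand
#' side, i.e. the number of reactions in which the species appears as a
#' reactant or product.  The network degree (the quantity the joint-table
#' cost is exponential in) is the maximum over species.
#'
#' @param network a [reaction_network()].
#' @param species_index 1-based species index.
#' @return integer degree.
#' @export
ode_degree <- function(network, species_index) {
  stopifnot(species_index >= 1, species_index <= n_species(network))
  sum(vapply(network$reactions, function(rx)
    species_index %in% c(rx$reactants, rx$products), logical(1)))
}

#' @rdname ode_degree
#' @export
network_degree <- function(network) {
  max(vapply(seq_along(network$species),
             function(i) ode_degree(network, i), 1L))
}

#' Parameters appearing in a species' ODE
#'
#' @inheritParams ode_degree
#' @return sorted integer vector of parameter indices of reactions touching
#'   the species (possibly empty).
#' @export
params_in_ode <- function(network, species_index) {
  stopifnot(species_index >= 1, species_index <= n_species(network))
  idx <- vapply(network$reactions, function(rx)
    if (species_index %in% c(rx$reactants, rx$products))
      as.integer(rx$param) else NA_integer_, 1L)
  sort(unique(idx[!is.na(idx)]))
}

#' Simulate a network trajectory
#'
#' Integrates the mass-action ODE system with a stiff-capable adaptive
#' solver (`deSolve::lsoda`, rtol 1e-8, atol 1e-10) so that data-generation
#' error is negligible relative to estimation error.
#'
#' @param network a [reaction_network()].
#' @param params numeric rate-parameter vector.
#' @param initial non-negative initial concentration vector.
#' @param timepoints strictly increasing times at which to report the state.
#' @param rtol,atol integrator tolerances.
#' @return A data frame with column `time` followed by one column per
#'   species (a trajectory in the package's CSV layout).
#' @examples
#' net <- parse_network("A -> B ; k")
#' tr <- simulate_network(net, 1, c(1, 0), seq(0, 4, 0.4))
#' max(abs(tr$A - exp(-tr$time)))  # ~1e-9
#' @export
simulate_network <- function(network, params, initial, timepoints,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(initial) == n_species(network),
            all(initial >= 0), all(diff(timepoints) > 0),
            length(timepoints) >= 2)
  derivs <- function(t, y, p) list(ode_rhs(network, p, y))
  sol <- deSolve::lsoda(y = stats::setNames(initial, network$species),
                        times = timepoints, func = derivs, parms = params,
                        rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  if (nrow(sol) != length(timepoints) || any(!is.finite(as.matrix(sol)))) {
    bad <- which(apply(!is.finite(as.matrix(sol[-1])), 2, any))
    stop("integration failed",
         if (length(bad)) paste0(" for species ",
                                 paste(network$species[bad], collapse = ", ")),
         " near t = ", sol$time[nrow(sol)])
  }
  names(sol) <- c("time", network$species)
  rownames(sol) <- NULL
  sol
}
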