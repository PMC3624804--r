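#' Ring network of unimolecular conversions
#'
#' Species `A1 ... An` arranged in a cycle, with reactions
#' `Ai -> A(i mod n)+1` and one rate parameter `ki` each.  Every ODE has
#' degree 2 (one inflow, one outflow) and total mass is conserved, making
#' rings the minimal scalable test bed for the factor-graph stage.
#'
#' @param n number of species (>= 2).
#' @return A [reaction_network()].
#' @export
make_ring_network <- function(n) {
  if (n < 2) stop("a ring needs at least 2 species")
  lines <- vapply(seq_len(n), function(i)
    sprintf("A%d -> A%d ; k%d", i, i %% n + 1L, i), character(1))
  parse_network(lines)
}

#' Random low-degree mass-action network
#'
#' Draws `round(2/3 * n_reactions)` bimolecular reactions
#' (`A + B -> C`, three distinct species) and the remainder unimolecular
#' conversions (`A -> B`), each with its own rate parameter.  Species are
#' sampled with probability proportional to remaining degree capacity so
#' no ODE exceeds `degree_cap` terms; generation is retried until every
#' species participates in at least one reaction.
#'
#' @param n_species number of species (>= 3).
#' @param n_reactions number of reactions (default `n_species`, keeping
#'   mean degree between 2 and 3).
#' @param seed integer seed; the same seed reproduces the same network.
#' @param degree_cap maximum reactions touching any one species.
#' @param max_tries retry budget before giving up.
#' @return A [reaction_network()].
#' @export
make_random_low_degree_network <- function(n_species,
                                           n_reactions = n_species,
                                           seed = 1, degree_cap = 4,
                                           max_tries = 200) {
  stopifnot(n_species >= 3, n_reactions >= 3)
  n_bi <- round(2 / 3 * n_reactions)
  n_uni <- n_reactions - n_bi
  touches <- 3 * n_bi + 2 * n_uni
  if (touches > degree_cap * n_species || touches < n_species)
    stop("infeasible constraints: ", n_reactions, " reactions cannot cover ",
         n_species, " species under degree cap ", degree_cap)
  .with_seed(seed, {
    for (try in seq_len(max_tries)) {
      deg <- integer(n_species)
      lines <- character(0)
      kinds <- sample(c(rep(TRUE, n_bi), rep(FALSE, n_uni)))
      ok <- TRUE
      for (r in seq_len(n_reactions)) {
        need <- if (kinds[r]) 3L else 2L
        cap <- which(deg < degree_cap)
        if (length(cap) < need) { ok <- FALSE; break }
        w <- degree_cap - deg[cap]
        # favour uncovered species so every species ends up used
        w <- w * ifelse(deg[cap] == 0, 4, 1)
        sp <- cap[sample.int(length(cap), need, prob = w)]
        deg[sp] <- deg[sp] + 1L
        lines <- c(lines, if (kinds[r])
          sprintf("S%d + S%d -> S%d ; k%d", sp[1], sp[2], sp[3], r)
        else sprintf("S%d -> S%d ; k%d", sp[1], sp[2], r))
      }
      if (ok && all(deg >= 1L)) {
        net <- parse_network(lines)
        if (n_species(net) == n_species && network_degree(net) <= degree_cap)
          return(net)
      }
    }
    stop("could not satisfy network constraints after ", max_tries, " tries")
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Akt signalling network topology
#'
#' A mass-action reconstruction of serum-stimulated Akt activation with
#' redox regulation of PTEN: serum activates PI3K; serum also drives
#' NOX-mediated production of reactive oxygen species (ROS), which are
#' degraded by antioxidants and reversibly inactivate the phosphatase
#' PTEN; PI3K converts PIP2 to PIP3 and PTEN reverses it; PIP3 recruits
#' Akt and PDK1 from the cytosol to the membrane (reversibly); membrane
#' PDK1 phosphorylates membrane Akt at Thr308; phospho-Akt returns to the
#' cytosol where PP2A dephosphorylates it.  The shipped rate constants are
#' synthetic unit-scale placeholders, chosen once so that all species show
#' informative transients on a 0-4 s window; supply `rates` to override.
#'
#' @param rates optional named numeric vector overriding the default rate
#'   constants (names must match the model's parameter names).
#' @return list with `$network` (a [reaction_network()]), `$params`
#'   (named nominal rate vector) and `$initial` (named default initial
#'   concentrations).
#' @export
make_akt_network <- function(rates = NULL) {
  lines <- c(
    "Serum + inactPI3K -> Serum + PI3K ; k_pi3k_act",
    "PI3K -> inactPI3K ; k_pi3k_deact",
    "Serum + NOX -> NOX + ROS ; k_ros_prod",
    "ROS -> 0 ; k_ros_deg",
    "ROS + PTEN -> ROS + inactPTEN ; k_pten_inact",
    "inactPTEN -> PTEN ; k_pten_react",
    "PI3K + PIP2 -> PI3K + PIP3 ; k_pip3_prod",
    "PTEN + PIP3 -> PTEN + PIP2 ; k_pip3_deg",
    "PIP3 + Aktcyto -> PIP3 + Aktmem ; k_akt_to_mem",
    "Aktmem -> Aktcyto ; k_akt_to_cyto",
    "PIP3 + PDK1cyto -> PIP3 + PDK1mem ; k_pdk1_to_mem",
    "PDK1mem -> PDK1cyto ; k_pdk1_to_cyto",
    "PDK1mem + Aktmem -> PDK1mem + Aktp308mem ; k_akt_phos",
    "Aktp308mem -> Aktp308cyto ; k_aktp_to_cyto",
    "PP2A + Aktp308cyto -> PP2A + Aktcyto ; k_akt_dephos")
  net <- parse_network(lines)
  # synthetic placeholder kinetics, unit scale (see package vignette)
  params <- c(k_pi3k_act = 0.8, k_pi3k_deact = 0.3, k_ros_prod = 0.6,
              k_ros_deg = 0.4, k_pten_inact = 0.7, k_pten_react = 0.2,
              k_pip3_prod = 0.9, k_pip3_deg = 0.5, k_akt_to_mem = 0.8,
              k_akt_to_cyto = 0.3, k_pdk1_to_mem = 0.6,
              k_pdk1_to_cyto = 0.2, k_akt_phos = 0.9,
              k_aktp_to_cyto = 0.4, k_akt_dephos = 0.5)
  stopifnot(identical(sort(names(params)), sort(net$param_names)))
  if (!is.null(rates)) {
    stopifnot(all(names(rates) %in% names(params)))
    params[names(rates)] <- rates
  }
  initial <- c(Serum = 1, inactPI3K = 0.8, PI3K = 0.1, NOX = 0.5,
               ROS = 0.05, PTEN = 0.7, inactPTEN = 0.1, PIP2 = 1,
               PIP3 = 0.05, Aktcyto = 0.9, Aktmem = 0.05,
               PDK1cyto = 0.8, PDK1mem = 0.05, Aktp308mem = 0.02,
               Aktp308cyto = 0.02, PP2A = 0.6)
  list(network = net,
       params = params[net$param_names],
       initial = initial[net$species])
}

#' Benchmark scenario description
#'
#' Bundles everything needed to generate a synthetic dataset: a network,
#' nominal parameters, a timepoint grid, a noise level and a seed.  The
#' seed fully determines the generated dataset.
#'
#' @param network a [reaction_network()].
#' @param params nominal rate-parameter vector.
#' @param times timepoint grid (default the standard 11 points on 0-4 s,
#'   0.4 s step).
#' @param noise relative noise level (fraction, e.g. 0.2 for 20%).
#' @param seed integer seed.
#' @param n_experiments number of experiments (independent initial
#'   conditions and noise draws).
#' @param initial optional fixed initial concentration vector (or matrix,
#'   one row per experiment); by default drawn uniformly on `[0.1, 1]`.
#' @param noise_model `"multiplicative"` (default): each observation is
#'   `x * (1 + noise * z)` with standard normal `z`, clipped at 0;
#'   `"additive"`: `x + noise * z`, clipped at 0.
#' @param snap_to_bins optional [discretize_parameters()] scheme; when
#'   given, nominal parameters are snapped to the nearest bin midpoints.
#' @return An object of class `benchmark_scenario`.
#' @export
benchmark_scenario <- function(network, params, times = seq(0, 4, by = 0.4),
                               noise = 0, seed = 1, n_experiments = 1,
                               initial = NULL,
                               noise_model = c("multiplicative", "additive"),
                               snap_to_bins = NULL) {
  stopifnot(length(params) == n_parameters(network), noise >= 0,
            n_experiments >= 1)
  if (!is.null(snap_to_bins)) params <- snap_to_midpoints(params, snap_to_bins)
  structure(list(network = network,
                 params = stats::setNames(as.numeric(params),
                                          network$param_names),
                 times = times, noise = noise, seed = as.integer(seed),
                 n_experiments = as.integer(n_experiments),
                 initial = initial,
                 noise_model = match.arg(noise_model)),
            class = "benchmark_scenario")
}

#' Generate a synthetic dataset from a scenario
#'
#' Simulates the network at the nominal parameters from seeded random
#' initial concentrations (uniform on `[0.1, 1]` unless fixed in the
#' scenario), observes every species on the timepoint grid, and applies
#' the scenario's noise model.  Noise level 0 returns the simulation
#' exactly.  The same scenario always yields a bit-identical dataset.
#'
#' @param scenario a [benchmark_scenario()].
#' @return A [time_series_dataset()].
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "benchmark_scenario"))
  net <- scenario$network
  ns <- n_species(net)
  .with_seed(scenario$seed, {
    exps <- list()
    for (r in seq_len(scenario$n_experiments)) {
      x0 <- if (is.null(scenario$initial)) {
        stats::runif(ns, 0.1, 1.0)
      } else if (is.matrix(scenario$initial)) {
        scenario$initial[r, ]
      } else scenario$initial
      sim <- simulate_network(net, scenario$params, x0, scenario$times)
      obs <- as.matrix(sim[, net$species, drop = FALSE])
      if (scenario$noise > 0) {
        z <- matrix(stats::rnorm(length(obs)), nrow(obs))
        obs <- if (scenario$noise_model == "multiplicative")
          obs * (1 + scenario$noise * z)
        else obs + scenario$noise * z
        obs <- pmax(obs, 0)
      }
      colnames(obs) <- net$species
      exps[[paste0("exp", r)]] <- list(times = scenario$times, obs = obs)
    }
    time_series_dataset(exps, species = net$species)
  })
}

#' Nominal parameters drawn from bin midpoints
#'
#' Samples one bin midpoint per parameter, reproducing the benchmark setup
#' in which the truth lies exactly on the discretization grid.
#'
#' @param scheme a [discretize_parameters()] scheme.
#' @param seed integer seed.
#' @return named numeric parameter vector.
#' @export
sample_midpoint_params <- function(scheme, seed = 1) {
  .with_seed(seed, {
    vapply(scheme, function(s) s$midpoints[sample.int(s$count, 1)],
           numeric(1))
  })
}
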