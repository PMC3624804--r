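# Shared fixture builders; everything is generated in code at test time.

toy_ab <- function() parse_network(c("A -> B ; k1", "B -> A ; k2"))

# noise-free dataset simulated from a network at `params`
toy_dataset <- function(network, params, x0, times = seq(0, 4, 0.4)) {
  tr <- simulate_network(network, params, x0, times)
  time_series_dataset(tr)
}

# hand-built derivative table (for exact-arithmetic error-term tests)
manual_derivs <- function(obs, deriv, times) {
  structure(list(deriv = list(exp1 = deriv), smooth = list(exp1 = obs),
                 is_boundary = list(exp1 = c(TRUE,
                                             rep(FALSE, length(times) - 2),
                                             TRUE)[seq_along(times)]),
                 smoothing = 0, boundary = "natural"),
            class = "deriv_table")
}

manual_dataset <- function(obs, times) {
  time_series_dataset(list(exp1 = list(times = times, obs = obs)))
}

# a one-factor factor graph over the given joint table (built by hand)
single_factor_graph <- function(n_params, vars, param_names = NULL) {
  if (is.null(param_names)) param_names <- paste0("k", seq_len(n_params))
  structure(list(factors = list(list(experiment = "exp1", species = 1L,
                                     species_name = "A", timepoint = 1L,
                                     vars = vars)),
                 n_params = n_params, param_names = param_names),
            class = "factor_graph")
}

manual_joint_table <- function(prob, vars) {
  structure(list(vars = vars, prob = prob, log_prob = log(prob),
                 beta = 1, cells = length(prob)), class = "joint_table")
}
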