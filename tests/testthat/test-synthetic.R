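test_that("ring networks have the stated size and uniform degree 2", {
  r3 <- make_ring_network(3)
  expect_equal(n_species(r3), 3L)
  expect_equal(n_reactions(r3), 3L)
  expect_equal(n_parameters(r3), 3L)
  r100 <- make_ring_network(100)
  expect_equal(n_parameters(r100), 100L)
  degs <- vapply(1:100, function(i) ode_degree(r100, i), 1L)
  expect_true(all(degs == 2L))
  expect_error(make_ring_network(1), "at least 2")
})

test_that("random low-degree networks respect the 2/3 split and the cap", {
  net <- make_random_low_degree_network(30, 30, seed = 4)
  kinds <- vapply(net$reactions, function(rx)
    length(rx$reactants) == 2L, logical(1))
  expect_equal(sum(kinds), 20L)   # two-thirds bimolecular
  expect_equal(sum(!kinds), 10L)
  expect_lte(network_degree(net), 4L)
  expect_equal(n_species(net), 30L)  # every species participates
  # same seed, same network
  net2 <- make_random_low_degree_network(30, 30, seed = 4)
  expect_identical(format_network(net), format_network(net2))
  net3 <- make_random_low_degree_network(30, 30, seed = 5)
  expect_false(identical(format_network(net), format_network(net3)))
  expect_error(make_random_low_degree_network(50, 9, degree_cap = 4),
               "infeasible|cover")
})

test_that("the Akt topology contains the pathway actors at low degree", {
  akt <- make_akt_network()
  net <- akt$network
  needed <- c("Serum", "PI3K", "inactPI3K", "NOX", "ROS", "PTEN",
              "inactPTEN", "PIP2", "PIP3", "Aktcyto", "Aktmem",
              "PDK1cyto", "PDK1mem", "Aktp308mem", "Aktp308cyto", "PP2A")
  expect_setequal(net$species, needed)
  expect_lte(network_degree(net), 4L)
  expect_equal(length(akt$params), n_parameters(net))
  # without ROS production (and no initial ROS) PTEN is never inactivated
  p0 <- akt$params; p0["k_ros_prod"] <- 0
  x0 <- akt$initial; x0["ROS"] <- 0; x0["inactPTEN"] <- 0
  tr <- simulate_network(net, p0, x0, seq(0, 4, 0.4))
  expect_lt(max(abs(tr$ROS)), 1e-9)
  expect_lt(max(abs(tr$inactPTEN)), 1e-9)
  # rate overrides are applied
  akt2 <- make_akt_network(rates = c(k_ros_prod = 0.123))
  expect_equal(unname(akt2$params["k_ros_prod"]), 0.123)
})

test_that("dataset generation is seed-reproducible and noise-calibrated", {
  net <- make_ring_network(5)
  truth <- sample_midpoint_params(discretize_parameters(net), seed = 3)
  sc <- benchmark_scenario(net, truth, noise = 0, seed = 3)
  d1 <- generate_dataset(sc)
  d2 <- generate_dataset(sc)
  expect_identical(d1, d2)
  # level 0 equals the simulation exactly
  x0 <- d1$experiments$exp1$obs[1, ]
  tr <- simulate_network(net, truth, x0, sc$times)
  expect_equal(d1$experiments$exp1$obs,
               as.matrix(tr[, net$species]), ignore_attr = TRUE)
  # multiplicative noise has the nominal relative spread
  x0 <- d1$experiments$exp1$obs[1, ]
  grid <- seq(0, 4, length.out = 500)
  dn <- generate_dataset(benchmark_scenario(net, truth, times = grid,
                                            noise = 0.2, seed = 8,
                                            initial = x0))
  clean <- as.matrix(simulate_network(net, truth, x0, grid)[, net$species])
  rel <- (dn$experiments$exp1$obs - clean) / clean
  expect_equal(sd(rel), 0.2, tolerance = 0.05)
})

test_that("mid-bin snapping lands every parameter on a midpoint", {
  net <- make_ring_network(4)
  sch <- discretize_parameters(net)
  sc <- benchmark_scenario(net, c(0.12, 0.48, 0.97, 0.33),
                           snap_to_bins = sch)
  expect_true(all(sc$params %in% unlist(lapply(sch, `[[`, "midpoints"))))
  mids <- sample_midpoint_params(sch, seed = 10)
  expect_true(all(mids %in% sch[[1]]$midpoints))
})
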