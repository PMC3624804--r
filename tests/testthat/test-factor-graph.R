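test_that("equidistant binning puts midpoints where expected", {
  b <- build_bins(0.05, 1.05, 10)
  expect_equal(b$width, 0.1)
  expect_equal(b$midpoints, seq(0.1, 1.0, by = 0.1))
  expect_equal(build_bins(0, 1, 2)$midpoints, c(0.25, 0.75))
  expect_warning(b1 <- build_bins(0, 1, 1), "single bin")
  expect_equal(b1$midpoints, 0.5)
  expect_error(build_bins(1, 1, 5), "width")
  expect_true(all(b$midpoints > b$lower & b$midpoints < b$upper))
})

test_that("factor-graph structure follows the dataset and the ODE adjacency", {
  net <- toy_ab()
  ds <- toy_dataset(net, c(0.4, 0.2), c(0.9, 0.1))
  g <- build_factor_graph(net, ds)
  expect_equal(length(g$factors), 22L)  # 2 species x 11 timepoints
  expect_true(all(vapply(g$factors, function(f)
    identical(f$vars, c(1L, 2L)), logical(1))))

  deg1 <- parse_network("A -> 0 ; k")
  ds1 <- toy_dataset(deg1, 0.5, 1)
  g1 <- build_factor_graph(deg1, ds1)
  expect_true(all(vapply(g1$factors, function(f)
    length(f$vars), 1L) == 1L))

  ring <- make_ring_network(10)
  dsr <- generate_dataset(benchmark_scenario(
    ring, sample_midpoint_params(discretize_parameters(ring), 1), seed = 1))
  gr <- build_factor_graph(ring, dsr)
  expect_equal(length(gr$factors), 110L)
  expect_true(all(vapply(gr$factors, function(f)
    length(f$vars), 1L) == 2L))
})

test_that("joint tables apply Boltzmann weighting and normalize exactly", {
  # 1-D factor with eps = {0, 1} at beta = 1
  net <- parse_network("A -> 0 ; k")
  obs <- matrix(2, 2, 1, dimnames = list(NULL, "A"))
  ds <- manual_dataset(obs, 0:1)
  dv <- manual_derivs(obs, matrix(-0.5, 2, 1), 0:1)
  sch <- discretize_parameters(net, 0, 1, bins = 2)
  g <- build_factor_graph(net, ds)
  tab <- compute_joint_table(g$factors[[1]], net, ds, dv, sch, beta = 1)
  expect_equal(as.numeric(tab$prob), c(1, exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(sum(tab$prob), 1, tolerance = 1e-12)

  # a flat error surface yields a uniform table (catalyst-style factor)
  dvf <- manual_derivs(obs, matrix(0, 2, 1), 0:1)
  cat_net <- parse_network("A -> A ; k")  # pure catalysis: zero net flux
  gcat <- build_factor_graph(cat_net, ds)
  tabf <- compute_joint_table(gcat$factors[[1]], cat_net, ds, dvf, sch)
  expect_equal(as.numeric(tabf$prob), c(0.5, 0.5))

  # tables match a brute-force evaluation through error_term
  ring <- make_ring_network(3)
  schr <- discretize_parameters(ring, 0.05, 1.05, 4)
  truth <- sample_midpoint_params(schr, seed = 5)
  dsr <- toy_dataset(ring, truth, c(0.9, 0.4, 0.2))
  dvr <- interpolated_derivatives(dsr)
  gr <- build_factor_graph(ring, dsr)
  f <- gr$factors[[8]]
  tabr <- compute_joint_table(f, ring, dsr, dvr, schr, beta = 2)
  eps <- matrix(0, 4, 4)
  for (b1 in 1:4) for (b2 in 1:4) {
    k <- truth
    k[f$vars] <- c(schr[[f$vars[1]]]$midpoints[b1],
                   schr[[f$vars[2]]]$midpoints[b2])
    eps[b1, b2] <- error_term(ring, k, dsr, dvr, f$experiment,
                              f$species_name, f$timepoint)
  }
  ref <- exp(-2 * eps); ref <- ref / sum(ref)
  expect_equal(tabr$prob, ref, tolerance = 1e-12)
  expect_equal(tabr$cells, 16)
})

test_that("table argmax and max-marginalization follow the definitions", {
  expect_equal(table_argmax(c(0.2, 0.5, 0.3)), 2L)
  expect_equal(table_argmax(rep(0.25, 4)), 1L)       # tie -> first
  u <- array(1 / 8, c(2, 2, 2))
  expect_equal(table_argmax(u), c(1L, 1L, 1L))
  a3 <- array(runif(27), c(3, 3, 3))
  brute <- as.integer(arrayInd(which.max(a3), dim(a3)))
  expect_equal(table_argmax(a3), brute)

  g <- matrix(c(1, 3, 2, 4), 2, 2)  # g[1,] = (1,2); g[2,] = (3,4)
  expect_equal(max_marginalize(g, 1), c(2, 4))
  expect_equal(max_marginalize(g, 2), c(3, 4))
  expect_equal(max_marginalize(c(5, 1, 7), 1), c(5, 1, 7))
  expect_equal(max_marginalize(array(2, c(2, 2)), 2), c(2, 2))
})

test_that("a single-factor graph is solved exactly by propagation", {
  set.seed(4)
  prob <- array(runif(8), c(2, 4)); prob <- prob / sum(prob)
  g <- single_factor_graph(2, c(1L, 2L))
  sch <- structure(list(build_bins(0, 1, 2), build_bins(0, 1, 4)),
                   class = "discretization")
  res <- run_lbp(g, list(manual_joint_table(prob, c(1L, 2L))), sch)
  expect_true(res$converged)
  expect_equal(res$estimate$bin, table_argmax(prob))
  expect_true(all(abs(vapply(res$beliefs, sum, numeric(1)) - 1) < 1e-12))
})

test_that("propagation recovers planted bins and is deterministic", {
  ring <- make_ring_network(6)
  sch <- discretize_parameters(ring)
  truth <- sample_midpoint_params(sch, seed = 2)
  ds <- generate_dataset(benchmark_scenario(ring, truth, seed = 2))
  r1 <- spedre_base(ring, ds, sch)
  r2 <- spedre_base(ring, ds, sch)
  expect_identical(r1$estimate, r2$estimate)
  expect_identical(r1$beliefs, r2$beliefs)
  expect_equal(midpoints_of(sch, r1$estimate$bin), unname(truth))
  expect_true(r1$converged)
  # complexity accounting: cells = sum over factors of bins^degree
  expected_cells <- sum(vapply(seq_len(n_species(ring)), function(i)
    10^length(params_in_ode(ring, i)), numeric(1))) * 11
  expect_identical(r1$cells, expected_cells)
})

test_that("equilibrium data yield near-uniform beliefs and a warning", {
  net <- toy_ab()
  obs <- matrix(0.5, 11, 2, dimnames = list(NULL, c("A", "B")))
  ds <- manual_dataset(obs, seq(0, 4, 0.4))
  expect_warning(res <- spedre_base(net, ds), "non-identifiable")
  expect_equal(res$degenerate, c("k1", "k2"))
})

test_that("the textbook exclusion rule and damping still solve easy cases", {
  ring <- make_ring_network(4)
  sch <- discretize_parameters(ring)
  truth <- sample_midpoint_params(sch, seed = 9)
  ds <- generate_dataset(benchmark_scenario(ring, truth, seed = 9))
  std <- spedre_base(ring, ds, sch, standard_bp = TRUE)
  dmp <- spedre_base(ring, ds, sch, damping = 0.3)
  expect_equal(midpoints_of(sch, std$estimate$bin), unname(truth))
  expect_equal(midpoints_of(sch, dmp$estimate$bin), unname(truth))
})

test_that("an empty factor graph is rejected", {
  g <- structure(list(factors = list(), n_params = 1,
                      param_names = "k"), class = "factor_graph")
  sch <- structure(list(build_bins(0, 1, 2)), class = "discretization")
  expect_error(run_lbp(g, list(), sch), "empty")
})
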