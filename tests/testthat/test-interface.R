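test_that("the fitting front door returns a full-featured model object", {
  net <- toy_ab()
  truth <- c(k1 = 0.45, k2 = 0.25)
  tr <- simulate_network(net, truth, c(0.9, 0.1), seq(0, 4, 0.4))
  fit <- spedre(net, tr)
  expect_s3_class(fit, "spedre")
  expect_equal(coef(fit), truth, tolerance = 1e-4)
  expect_output(print(fit), "Coefficients")
  s <- summary(fit)
  expect_s3_class(s, "summary.spedre")
  expect_output(print(s), "joint-table cells")
  expect_equal(s$table$map_bin, c(5L, 3L))  # midpoints 0.5 and 0.3

  pr <- predict(fit)
  expect_equal(pr$time, tr$time)
  expect_equal(pr$A, tr$A, tolerance = 1e-4)
  res <- residuals(fit)
  expect_lt(max(abs(res$exp1)), 1e-4)
  sims <- simulate(fit, nsim = 2, seed = 5, noise = 0.1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "spedre_data")
  expect_false(identical(sims[[1]], sims[[2]]))

  png_path <- file.path(tempdir(), "fit.png")
  grDevices::png(png_path)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(png_path))
  unlink(png_path)

  # base-only fit keeps the MAP midpoints as coefficients
  base_only <- spedre(net, tr, refine = FALSE)
  expect_equal(unname(coef(base_only)), c(0.5, 0.3))
})

test_that("text and file model inputs are accepted by the front door", {
  truth <- c(0.45, 0.25)
  net <- toy_ab()
  tr <- simulate_network(net, truth, c(0.9, 0.1), seq(0, 4, 0.4))
  fit <- spedre(c("A -> B ; k1", "B -> A ; k2"), tr)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-4)
})

test_that("the CLI round-trips generate -> estimate with provenance", {
  out1 <- file.path(tempdir(), "cli_gen")
  out2 <- file.path(tempdir(), "cli_est")
  on.exit(unlink(c(out1, out2), recursive = TRUE), add = TRUE)
  suppressMessages(spedre_cli(c("generate", "--network", "ring",
                                "--n", "4", "--seed", "3",
                                "--out", out1)))
  expect_true(file.exists(file.path(out1, "model.txt")))
  expect_true(file.exists(file.path(out1, "exp1.csv")))
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seed, 3)

  suppressMessages(spedre_cli(c("estimate",
                                "--model", file.path(out1, "model.txt"),
                                "--data", file.path(out1, "exp1.csv"),
                                "--truth", file.path(out1, "manifest.json"),
                                "--out", out2)))
  for (f in c("map.json", "refinement.json", "score.json",
              "convergence.csv", "run_config.json"))
    expect_true(file.exists(file.path(out2, f)), label = f)
  score <- jsonlite::read_json(file.path(out2, "score.json"),
                               simplifyVector = TRUE)
  expect_lt(score$median_ppe, 1)  # noise-free fixture recovered
  # rerun is bit-identical
  map1 <- readLines(file.path(out2, "map.json"))
  suppressMessages(spedre_cli(c("estimate",
                                "--model", file.path(out1, "model.txt"),
                                "--data", file.path(out1, "exp1.csv"),
                                "--out", out2)))
  expect_identical(readLines(file.path(out2, "map.json")), map1)
})

test_that("the CLI rejects incomplete data and unknown commands", {
  expect_error(spedre_cli(character()), "usage")
  expect_error(spedre_cli("frobnicate"), "unknown subcommand")
  out <- file.path(tempdir(), "cli_bad")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  suppressMessages(spedre_cli(c("generate", "--network", "ring", "--n", "3",
                                "--seed", "1", "--out", out)))
  # drop a species column: the dense-data requirement must be enforced
  df <- read_trajectory_csv(file.path(out, "exp1.csv"))
  write_trajectory_csv(df[, 1:2], file.path(out, "exp1.csv"))
  expect_error(suppressMessages(
    spedre_cli(c("estimate", "--model", file.path(out, "model.txt"),
                 "--data", file.path(out, "exp1.csv")))),
    "data-rich")
})

test_that("simulate and score subcommands operate on files", {
  dir <- file.path(tempdir(), "cli_sim")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  writeLines(c("A -> B ; k1", "B -> A ; k2"), file.path(dir, "model.txt"))
  jsonlite::write_json(list(k1 = 0.45, k2 = 0.25),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(A = 0.9, B = 0.1),
                       file.path(dir, "x0.json"), auto_unbox = TRUE)
  suppressMessages(spedre_cli(c("simulate",
                                "--model", file.path(dir, "model.txt"),
                                "--params", file.path(dir, "params.json"),
                                "--initial", file.path(dir, "x0.json"),
                                "--out", file.path(dir, "traj.csv"))))
  tr <- read_trajectory_csv(file.path(dir, "traj.csv"))
  expect_equal(names(tr), c("time", "A", "B"))
  suppressMessages(spedre_cli(c("score",
                                "--model", file.path(dir, "model.txt"),
                                "--data", file.path(dir, "traj.csv"),
                                "--params", file.path(dir, "params.json"),
                                "--truth", file.path(dir, "params.json"),
                                "--out", file.path(dir, "score.json"))))
  sc <- jsonlite::read_json(file.path(dir, "score.json"),
                            simplifyVector = TRUE)
  expect_lt(sc$weighted_sse, 1e-8)
  expect_equal(sc$median_ppe, 0)
})
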