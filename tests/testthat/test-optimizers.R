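quad <- function(x) (x - 2)^2
two_basin <- function(x) -0.5 * exp(-2 * (x - 1)^2) - 1.0 * exp(-2 * (x - 7)^2)
box10 <- search_space(0, 10)

test_that("both optimizers recover a convex minimum", {
  ga <- ga_minimize(quad, box10, ga_config(50, 30, seed = 1))
  pso <- pso_minimize(quad, box10, pso_config(50, 30, seed = 1))
  expect_lt(abs(ga$par - 2), 1e-2)
  expect_lt(abs(pso$par - 2), 1e-3)
})

test_that("search spaces validate and transform correctly", {
  expect_error(search_space(1, 1), "invalid space")
  expect_error(search_space(-1, 1, "log"), "invalid space")
  sp <- search_space(1e-4, 1e2, "log")
  r <- pso_minimize(function(g) (log10(g) + 1)^2, sp,
                    pso_config(40, 20, seed = 2))
  expect_lt(abs(r$par - 0.1), 0.01)
})

test_that("best-so-far traces are monotone and budgets exact", {
  for (s in 1:5) {
    ga <- ga_minimize(two_basin, box10, ga_config(20, 10, seed = s))
    pso <- pso_minimize(two_basin, box10, pso_config(20, 10, seed = s))
    for (r in list(ga, pso)) {
      expect_true(all(diff(r$trace) <= 0))
      expect_equal(r$value, min(r$trace))
      expect_equal(length(r$trace), 21)
      expect_lte(r$n_evals, 10 * 21)
    }
  }
})

test_that("all evaluated candidates respect the bounds", {
  seen <- new.env(); seen$x <- numeric()
  watch <- function(x) { seen$x <- c(seen$x, x); (x - 3)^2 }
  ga_minimize(watch, search_space(2, 5), ga_config(15, 8, seed = 3))
  pso_minimize(watch, search_space(2, 5), pso_config(15, 8, seed = 3))
  expect_true(all(seen$x >= 2 & seen$x <= 5))
})

test_that("degenerate dynamics return the best initial candidate", {
  init <- matrix(c(1.5, 6, 9), ncol = 1)
  ga <- ga_minimize(two_basin, box10,
                    ga_config(10, 3, crossover_fraction = 0,
                              mutation_rate = 0, seed = 4),
                    init = init)
  pso <- pso_minimize(two_basin, box10,
                      pso_config(10, 3, cognitive = 0, social = 0,
                                 velocity_clamp = 0, seed = 4),
                      init = init)
  best0 <- init[which.min(two_basin(init)), 1]
  expect_equal(ga$par, best0)
  expect_equal(pso$par, best0)
})

test_that("non-finite objective values are penalized, not fatal", {
  nasty <- function(x) if (x < 5) NaN else (x - 7)^2
  r <- ga_minimize(nasty, box10, ga_config(25, 15, seed = 5))
  expect_lt(abs(r$par - 7), 0.2)
})

test_that("optimizers are deterministic under their seed", {
  a <- ga_minimize(two_basin, box10, ga_config(15, 10, seed = 9))
  b <- ga_minimize(two_basin, box10, ga_config(15, 10, seed = 9))
  expect_identical(a, b)
  a <- pso_minimize(two_basin, box10, pso_config(15, 10, seed = 9))
  b <- pso_minimize(two_basin, box10, pso_config(15, 10, seed = 9))
  expect_identical(a, b)
})

test_that("default configs carry the published budgets", {
  ga <- ga_config()
  expect_equal(ga$max_iterations, 500)
  expect_equal(ga$population_size, 100)
  expect_equal(ga$crossover_fraction, 0.5)
  pso <- pso_config()
  expect_equal(pso$max_iterations, 100)
  expect_equal(pso$population_size, 200)
  expect_equal(pso$inertia, 1)
  expect_equal(pso$cognitive, 1)
  expect_error(ga_config(population_size = 1), "invalid config")
  expect_error(pso_config(inertia = -1), "invalid config")
})

test_that("GA produces the configured number of crossover offspring", {
  # crossover_fraction 0.5, pop 10, elitism 1 -> 5 blend children, 4 copies
  cfg <- ga_config(1, 10, crossover_fraction = 0.5, mutation_rate = 0,
                   elitism = 1, seed = 6)
  r <- ga_minimize(quad, box10, cfg)
  expect_equal(r$n_evals, 20)  # pop x (iters + 1)
})

test_that("tuning the SVM never loses to the untuned default", {
  tab <- stock_table()
  feats <- feature_groups()$miRNA
  for (s in 1:2) {
    base <- tune_svm(tab, "drought", feats, "gaussian", "none", seed = s)
    tuned <- tune_svm(tab, "drought", feats, "gaussian", "ga",
                      config = ga_config(6, 6), seed = s)
    expect_lte(tuned$report$mse, base$report$mse + 1e-12)
  }
  t1 <- tune_svm(tab, "drought", feats, "gaussian", "pso",
                 config = pso_config(4, 6), seed = 1)
  t2 <- tune_svm(tab, "drought", feats, "gaussian", "pso",
                 config = pso_config(4, 6), seed = 1)
  expect_identical(t1$par, t2$par)
  expect_identical(t1$report$mse, t2$report$mse)
})

test_that("tuned linear-kernel SVR solves a one-feature noiseless signal", {
  m <- as.data.frame(default_response_model())
  m$noise_sd[] <- 1e-3
  m[m$feature != "miR477b", c("drought_slope", "salinity_slope")] <- 0
  m$direction[] <- "mixed"
  tab <- simulate_features(stress_design(), response_model(m), seed = 2)
  r <- tune_svm(tab, "drought", "miR477b", "linear", "ga",
                config = ga_config(8, 8), seed = 2)
  expect_gt(r$report$r_squared, 0.99)
})
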