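test_that("all four kernels are symmetric and the gaussian is bounded", {
  set.seed(21)
  X <- matrix(rnorm(40), 8, 5)
  specs <- list(kernel_spec("linear"), kernel_spec("polynomial", gamma = 0.7),
                kernel_spec("gaussian", gamma = 0.3),
                kernel_spec("sigmoid", gamma = 0.2, coef0 = 0.5))
  for (sp in specs) {
    K <- kernel_matrix(sp, X)
    expect_equal(K, t(K), tolerance = 1e-12)
  }
  Kg <- kernel_matrix(kernel_spec("gaussian", gamma = 0.3), X)
  expect_true(all(Kg > 0 & Kg <= 1))
  expect_equal(diag(Kg), rep(1, 8))
})

test_that("kernel specs validate their parameters", {
  expect_error(kernel_spec("gaussian", gamma = -1), "gamma")
  expect_error(kernel_spec("polynomial", degree = 1), "degree")
  expect_error(kernel_spec("spline"))
})

test_that("a linear signal is fit nearly exactly", {
  x <- matrix(seq(0, 3, length.out = 60))
  y <- 2 * x[, 1]
  fit <- svr_fit(x, y, kernel_spec("linear"), C = 10)
  expect_gt(r_squared(y, predict(fit, x)), 0.99)
})

test_that("gamma -> 0 drives gaussian predictions to a constant", {
  set.seed(4)
  X <- matrix(rnorm(60), 30, 2)
  y <- rnorm(30, sd = 2)
  fit <- svr_fit(X, y, kernel_spec("gaussian", gamma = 1e-9))
  p <- predict(fit, X)
  expect_lt(sd(p), 1e-3)
})

test_that("a gaussian kernel beats the linear kernel on an XOR pattern", {
  set.seed(6)
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  X <- as.matrix(g[rep(1:4, each = 10), ]) + matrix(rnorm(80, sd = 0.05), 40, 2)
  y <- as.numeric(xor(g$a[rep(1:4, each = 10)] > 0.5,
                      g$b[rep(1:4, each = 10)] > 0.5))
  lin <- svr_fit(X, y, kernel_spec("linear"), C = 10)
  rbf <- svr_fit(X, y, kernel_spec("gaussian", gamma = 2), C = 10)
  expect_lt(mse(y, predict(rbf, X)), mse(y, predict(lin, X)))
})

test_that("degenerate targets are rejected", {
  expect_error(svr_fit(matrix(1:5), rep(1, 5), kernel_spec("linear")),
               "degenerate targets")
})

test_that("prediction is invariant to feature order", {
  tab <- stock_table()
  X <- as.matrix(as.data.frame(tab)[, c("miR477b", "miR166i", "CA")])
  fit <- svr_fit(X, tab$drought, kernel_spec("gaussian"))
  p1 <- predict(fit, X)
  p2 <- predict(fit, X[, c("CA", "miR477b", "miR166i")])
  expect_equal(p1, p2)
})

test_that("scenario targets and row subsets follow the encoding", {
  expect_equal(encode_target("drought", 2, 0), 2)
  expect_equal(encode_target("salinity", 0, 3), 3)
  expect_equal(encode_target("combined", 3, 1), cbind(w = 3, s = 1))
  expect_error(encode_target("drought", 5, 0), "0..3")

  tab <- stock_table()
  expect_equal(sum(scenario_rows(tab, "drought")), 60)
  expect_equal(sum(scenario_rows(tab, "salinity")), 60)
  expect_equal(sum(scenario_rows(tab, "combined")), 240)
  expect_equal(sum(scenario_rows(tab, "drought", subset = "all")), 240)
  expect_true(all(tab$salinity[scenario_rows(tab, "drought")] == 0))
})

test_that("scenario evaluation is deterministic under a seed", {
  tab <- stock_table()
  r1 <- svm_evaluate(tab, "combined", features = feature_groups()$miRNA,
                     kernel = kernel_spec("linear"), seed = 3)
  r2 <- svm_evaluate(tab, "combined", features = feature_groups()$miRNA,
                     kernel = kernel_spec("linear"), seed = 3)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$mse, r2$mse)
})

test_that("shuffled targets give no out-of-sample skill", {
  tab <- stock_table()
  feats <- feature_groups()$miRNA
  r2s <- sapply(1:12, function(s) {
    shuffled <- tab
    perm <- with_seed_for_tests(s, sample(nrow(tab)))
    shuffled$drought <- tab$drought[perm]
    shuffled$salinity <- tab$salinity[perm]
    svm_evaluate(shuffled, "combined", features = feats,
                 kernel = kernel_spec("linear"), seed = s)$r_squared
  })
  expect_gte(sum(r2s < 0.1), 11)
  expect_lt(median(r2s), 0.05)
})

test_that("less generator noise never hurts median CV performance", {
  scale_noise <- function(fac) {
    m <- as.data.frame(default_response_model())
    m$noise_sd <- m$noise_sd * fac
    response_model(m)
  }
  med_r2 <- sapply(c(0.5, 1, 2), function(fac) {
    m <- scale_noise(fac)
    median(sapply(1:5, function(s) {
      tab <- simulate_features(stress_design(), m, seed = s)
      svm_evaluate(tab, "combined", features = feature_groups()$miRNA,
                   kernel = kernel_spec("linear"), seed = s)$r_squared
    }))
  })
  expect_true(all(diff(med_r2) <= 0))
})
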