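additive_v <- function(w) function(m) sum(w[m])

test_that("the exact engine reproduces textbook games", {
  w <- c(a = 1, b = 2, c = 3)
  r <- banzhaf_exact(names(w), additive_v(w))
  expect_equal(r$table$raw, c(1, 2, 3))
  expect_equal(r$table$share, c(100 / 6, 200 / 6, 300 / 6))

  maj <- banzhaf_exact(c("a", "b", "c"),
                       function(m) as.numeric(length(m) >= 2))
  expect_equal(maj$table$raw, rep(0.5, 3))
  expect_equal(maj$table$share, rep(100 / 3, 3))

  # dummy player: v ignores c entirely
  dum <- banzhaf_exact(c("a", "b", "c"),
                       function(m) sum(c(a = 2, b = 1)[intersect(m, c("a", "b"))]))
  expect_equal(dum$table$raw[dum$table$feature == "c"], 0)
})

test_that("exchangeable players get equal indices", {
  sym <- banzhaf_exact(letters[1:4], function(m) length(m)^2)
  expect_true(all(abs(sym$table$raw - sym$table$raw[1]) < 1e-12))
})

test_that("the Banzhaf index is linear in the game", {
  set.seed(14)
  feats <- letters[1:5]
  rand_game <- function() {
    vals <- new.env()
    function(m) {
      key <- paste0("k", paste(sort(m), collapse = ""))
      if (is.null(vals[[key]])) vals[[key]] <- rnorm(1)
      vals[[key]]
    }
  }
  v1 <- rand_game(); v2 <- rand_game()
  b1 <- banzhaf_exact(feats, v1)$table$raw
  b2 <- banzhaf_exact(feats, v2)$table$raw
  b12 <- banzhaf_exact(feats, function(m) v1(m) + v2(m))$table$raw
  expect_equal(b12, b1 + b2, tolerance = 1e-12)
})

test_that("each coalition is evaluated exactly once via the cache", {
  calls <- new.env(); calls$n <- 0
  v <- function(m) { calls$n <- calls$n + 1; length(m) }
  banzhaf_exact(letters[1:4], v)
  expect_equal(calls$n, 2^4)
})

test_that("the Monte Carlo estimator agrees with the exact engine", {
  set.seed(15)
  feats <- letters[1:6]
  for (rep in 1:2) {
    vals <- stats::setNames(rnorm(6, sd = 2), feats)
    v <- function(m) sum(vals[m]) + 0.3 * length(m)^1.5
    ex <- banzhaf_exact(feats, v)
    mc <- banzhaf_monte_carlo(feats, v, n_samples = 400, seed = rep)
    ok <- abs(mc$table$raw - ex$table$raw) <=
      3 * pmax(mc$table$se, 1e-9) + 1e-9
    expect_true(all(ok))
  }
})

test_that("Monte Carlo error shrinks roughly as 1/sqrt(samples)", {
  feats <- letters[1:5]
  vals <- stats::setNames(c(1, -2, 3, 0.5, 2), feats)
  v <- function(m) sum(vals[m]) + 0.2 * length(m)^2
  ex <- banzhaf_exact(feats, v)$table$raw
  err <- function(ns) {
    mean(sapply(1:8, function(s)
      max(abs(banzhaf_monte_carlo(feats, v, ns, seed = s)$table$raw - ex))))
  }
  e1 <- err(50); e2 <- err(800)
  expect_lt(e2, e1 * 0.6)   # x16 samples should cut the error well below half
})

test_that("Monte Carlo estimates are deterministic under a seed", {
  v <- additive_v(c(a = 1, b = 2, c = 3))
  m1 <- banzhaf_monte_carlo(c("a", "b", "c"), v, 100, seed = 7)
  m2 <- banzhaf_monte_carlo(c("a", "b", "c"), v, 100, seed = 7)
  expect_identical(m1$table, m2$table)
})

test_that("share normalization floors negatives and rejects all-zero", {
  expect_equal(normalize_shares(c(0.5, 0.5, 0.5)), rep(100 / 3, 3))
  expect_equal(normalize_shares(c(3, 1, 0)), c(75, 25, 0))
  expect_equal(normalize_shares(c(2, -1, 2)), c(50, 0, 50))
  expect_error(normalize_shares(c(0, -1)), "undefined shares")
})

test_that("oversized groups are directed to the Monte Carlo estimator", {
  expect_error(banzhaf_exact(paste0("f", 1:16), function(m) 0),
               "banzhaf_monte_carlo")
})

test_that("the CV characteristic function behaves at its edges", {
  tab <- stock_table()
  v <- performance_characteristic(tab, "drought", kernel_spec("linear"),
                                  seed = 1)
  expect_equal(v(character(0)), 0)
  v1 <- v("miR477b")
  expect_true(is.finite(v1) && v1 <= 1)
  # fixed folds: repeated evaluation of the same coalition is identical
  expect_identical(v1, v("miR477b"))
  # full miRNA set does at least as well as the best singleton (median
  # property is tested end-to-end; here one seed, weak inequality vs all
  # singletons' max with tolerance)
  vf <- v(feature_groups()$miRNA)
  expect_gt(vf, v1 - 0.05)
})
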