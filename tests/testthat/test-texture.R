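test_that("grayscale conversion uses the documented luminance weights", {
  v <- array(0.5, dim = c(3, 3, 3))
  g <- to_grayscale(v)
  expect_equal(unclass(g)[, ], matrix(0.5, 3, 3), ignore_attr = TRUE)

  black <- array(0, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(black) == 0))

  rgb <- array(0, dim = c(2, 2, 3))
  rgb[1, 1, ] <- c(100, 50, 10)
  rgb[2, 2, ] <- c(0, 0, 200)
  g2 <- to_grayscale(rgb)
  expect_equal(g2[1, 1], 0.299 * 100 + 0.587 * 50 + 0.114 * 10)
  expect_equal(g2[2, 2], 0.114 * 200)

  expect_error(to_grayscale(matrix(1, 3, 3)), "format error")
})

test_that("closed-form GLCM statistics are reproduced", {
  # constant image: one co-occurrence class
  cc <- compute_glcm(matrix(7, 6, 6), levels = 4)
  expect_equal(sum(cc$p == 1), 1)
  expect_equal(glcm_entropy(cc), 0)
  expect_equal(glcm_energy(cc), 1)
  expect_equal(glcm_homogeneity(cc), 1)

  # checkerboard: p(0,1) = p(1,0) = 0.5
  g <- compute_glcm(checkerboard_img(8), levels = 2)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(glcm_entropy(g), log(2))
  expect_equal(glcm_entropy(g, base = "2"), 1)
  expect_equal(glcm_energy(g), 0.5)
  expect_equal(glcm_homogeneity(g), 0.5)

  # uniform over 4 cells
  u <- matrix(0.25, 2, 2)
  expect_equal(glcm_entropy(u), log(4))
  expect_equal(glcm_energy(u), 0.25)

  # all mass on the diagonal / at |i-j| = 1
  expect_equal(glcm_homogeneity(diag(2) / 2), 1)
  expect_equal(glcm_homogeneity(matrix(c(0, 0.5, 0.5, 0), 2, 2)), 0.5)
})

test_that("the printed 4x4 fixture matches exhaustive pair enumeration", {
  for (sym in c(TRUE, FALSE)) {
    got <- compute_glcm(fixture_4x4, levels = 2, offset = c(0, 1),
                        symmetric = sym)
    expect_equal(got$p, brute_glcm(fixture_4x4, 2, c(0, 1), symmetric = sym))
  }
})

test_that("GLCM agrees with the brute-force oracle on random images", {
  set.seed(42)
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (i in 1:30) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    G <- sample(2:8, 1)
    img <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
    mask <- if (i %% 3 == 0)
      matrix(sample(c(TRUE, TRUE, TRUE, FALSE), nr * nc, replace = TRUE),
             nr, nc) else NULL
    off <- offsets[[sample(4, 1)]]
    sym <- i %% 2 == 0
    got <- tryCatch(
      compute_glcm(img, levels = G, offset = off, symmetric = sym,
                   mask = mask),
      error = function(e) NULL)
    want <- tryCatch(brute_glcm(img, G, off, sym, mask),
                     error = function(e) NULL)
    if (is.null(got)) {
      expect_true(is.null(want) || !is.finite(sum(want)))
      next
    }
    expect_equal(got$p, want, tolerance = 1e-12)
    expect_equal(sum(got$p), 1, tolerance = 1e-12)
    expect_true(all(got$p >= 0))
    if (sym) expect_equal(got$p, t(got$p))
  }
})

test_that("entropy is maximal and energy minimal for the uniform GLCM", {
  set.seed(9)
  for (i in 1:10) {
    G <- sample(2:6, 1)
    p <- matrix(stats::rexp(G * G), G, G)
    p <- p / sum(p)
    u <- matrix(1 / G^2, G, G)
    expect_lte(glcm_entropy(p), glcm_entropy(u) + 1e-12)
    expect_gte(glcm_energy(p), glcm_energy(u) - 1e-12)
  }
})

test_that("features are invariant to a gray offset with matching range", {
  img <- matrix(sample(0:200, 100, replace = TRUE), 10, 10)
  f1 <- extract_texture_features(img, range = c(0, 255))
  f2 <- extract_texture_features(img + 40, range = c(40, 295))
  expect_equal(f1, f2)
})

test_that("degenerate and invalid GLCM inputs error", {
  expect_error(compute_glcm(matrix(1, 4, 4), levels = 1), "gray levels")
  expect_error(compute_glcm(matrix(1, 4, 4), offset = c(0, 0)), "offset")
  expect_error(compute_glcm(matrix(1, 2, 2), offset = c(0, 5)),
               "degenerate input")
  expect_error(
    compute_glcm(matrix(1, 4, 4), mask = matrix(FALSE, 4, 4)),
    "degenerate input")
  expect_error(glcm_entropy(matrix(0.3, 2, 2)), "contract violation")
})

test_that("direction averaging produces a valid feature vector", {
  img <- checkerboard_img(8)
  f <- extract_texture_features(img, average_directions = TRUE, levels = 2)
  expect_true(all(is.finite(f)))
  expect_lte(f["energy"], 1)
  expect_lte(f["homogeneity"], 1)
})

test_that("leaf segmentation matches the threshold oracle on a disc", {
  img <- matrix(20, 48, 48)
  yy <- row(img); xx <- col(img)
  img[(yy - 24)^2 + (xx - 24)^2 <= 14^2] <- 200
  mask <- segment_leaf(img)
  oracle <- img > 110
  band <- abs(sqrt((yy - 24)^2 + (xx - 24)^2) - 14) <= 2
  expect_equal(sum(mask != oracle & !band), 0)

  expect_warning(m2 <- segment_leaf(matrix(5, 32, 32)), "empty mask")
  expect_true(all(m2))
  expect_true(attr(m2, "empty"))

  lf <- simulate_leaf_image(48, 48, leaf_shape = TRUE, seed = 2)
  frac <- mean(segment_leaf(lf))
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("masked GLCM uses only in-mask pairs", {
  img <- matrix(c(rep(0, 24), rep(255, 24)), 6, 8)
  mask <- matrix(FALSE, 6, 8); mask[, 1:4] <- TRUE   # only the dark half
  g <- compute_glcm(img, levels = 2, mask = mask)
  expect_equal(g$p[1, 1], 1)  # all pairs are (0, 0)
})
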