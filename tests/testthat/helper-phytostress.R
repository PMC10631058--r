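# Shared fixtures and independent oracles.

# Brute-force GLCM oracle: enumerate every pixel pair explicitly.
brute_glcm <- function(img, levels, offset, symmetric = TRUE, mask = NULL,
                       range = c(0, 255)) {
  q <- floor((img - range[1]) / (range[2] - range[1]) * levels)
  q <- pmin(pmax(q, 0), levels - 1)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
      if (!mask[r, c] || !mask[r2, c2]) next
      counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# 2x2-tiled checkerboard image of 0s and 255s
checkerboard_img <- function(n = 8) {
  matrix(ifelse((row(matrix(0, n, n)) + col(matrix(0, n, n))) %% 2 == 0,
                0, 255), n, n)
}

with_seed_for_tests <- function(seed, expr) withr::with_seed(seed, expr)

# small 240-row default dataset shared by several files
stock_table <- function(seed = 42) simulate_features(stress_design(), seed = seed)

# 4x4 two-level fixture printed by hand (values 0/255 -> levels 0/1)
fixture_4x4 <- matrix(c(
  0,   0,   255, 255,
  0,   0,   255, 255,
  0,   255, 255, 0,
  255, 255, 0,   0), 4, 4, byrow = TRUE)
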