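# Small image-processing primitives (shift-based, vectorized).

# shift a matrix by (dr, dc) with replicate padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate padding
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(img, (i - 1L) - r, 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (i in seq_along(k)) out2 <- out2 + k[i] * shift_mat(out, 0L, (i - 1L) - r)
  out2
}

# Sobel gradients (gy: down-positive row gradient, gx: right-positive)
sobel_gradients <- function(img) {
  sx <- function(m) {
    (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) * 2 +
      (shift_mat(m, -1, -1) - shift_mat(m, -1, 1)) +
      (shift_mat(m, 1, -1) - shift_mat(m, 1, 1))
  }
  gx <- sx(img)
  gy <- t(sx(t(img)))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

dilate3 <- function(b) {
  out <- b
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out | shift_mat(b, dr, dc)
  out
}

erode3 <- function(b) {
  out <- b
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) out <- out & shift_mat(b, dr, dc)
  out
}

morph_close <- function(b) erode3(dilate3(b))

# 4-connected component labelling by iterative label propagation.
# Returns an integer matrix, 0 = background.
connected_components <- function(b) {
  lab <- matrix(0L, nrow(b), ncol(b))
  lab[b] <- seq_len(sum(b))
  # propagate the minimum positive label among 4-neighbours to fixpoint
  repeat {
    nb <- lab
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      s <- shift_mat(lab, d[1], d[2])
      take <- b & s > 0L & (nb == 0L | s < nb)
      nb[take] <- s[take]
    }
    if (all(nb == lab)) break
    lab <- nb
  }
  # compact labels
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

largest_component <- function(b) {
  lab <- connected_components(b)
  if (!any(lab > 0L)) return(matrix(FALSE, nrow(b), ncol(b)))
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}
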