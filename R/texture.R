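# GLCM texture statistics: entropy, energy, local homogeneity.

#' Convert an RGB array to grayscale
#'
#' Uses the video-luminance weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img Numeric array `height x width x 3`.
#' @return Gray matrix of the same height/width, carrying the input's
#'   `range` attribute (default `c(0, 255)`).
#' @export
to_grayscale <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("format error: expected a height x width x 3 RGB array")
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray_image(g, range = attr(img, "range") %||% c(0, 255))
}

#' Quantize gray values into G levels
#'
#' Equal-width bins spanning the declared gray range, so features are
#' invariant to a constant gray offset applied to both the image and its
#' declared range.
#'
#' @param img Gray matrix; declared range taken from its `range`
#'   attribute unless `range` is given.
#' @param levels Number of gray levels G (>= 2).
#' @param range Length-2 numeric, the declared value range.
#' @return Integer matrix with values in `0..levels-1`.
#' @export
quantize_gray <- function(img, levels = 8,
                          range = attr(img, "range") %||% c(0, 255)) {
  if (levels < 2) stop("invalid argument: need at least 2 gray levels")
  span <- range[2] - range[1]
  if (span <= 0) stop("invalid argument: declared range is empty")
  q <- floor((unclass(img) - range[1]) / span * levels)
  q <- pmin(pmax(q, 0), levels - 1)
  matrix(as.integer(q), nrow(img), ncol(img))
}

#' Gray-level co-occurrence matrix
#'
#' Counts how often quantized gray level i sits at displacement `offset`
#' from gray level j, over pixel pairs whose both members lie inside
#' `mask`, then normalizes to a probability matrix p(i, j). With
#' `symmetric = TRUE` the transpose counts are added before normalizing,
#' so each unordered neighbouring pair contributes in both directions.
#'
#' @param img Gray matrix (or already-quantized integer matrix when
#'   `quantized = TRUE`).
#' @param levels Number of gray levels G.
#' @param offset Integer `(row, col)` displacement; `c(0, 1)` is the
#'   horizontal right-neighbour.
#' @param symmetric Add the transpose before normalizing (default TRUE).
#' @param mask Optional logical matrix; pairs with either pixel outside
#'   the mask are discarded.
#' @param range Declared gray range used for quantization.
#' @param quantized Set TRUE if `img` already holds levels `0..G-1`.
#' @return Object of class `glcm`: list with the probability matrix `p`
#'   (G x G), `levels`, `offset`, `symmetric`, and `n_pairs` (raw pair
#'   count before symmetrization).
#' @export
#' @examples
#' g <- compute_glcm(matrix(c(0, 255, 0, 255), 2, 2), levels = 2)
#' g$p
compute_glcm <- function(img, levels = 8, offset = c(0, 1),
                         symmetric = TRUE, mask = NULL,
                         range = attr(img, "range") %||% c(0, 255),
                         quantized = FALSE) {
  if (levels < 2) stop("invalid argument: need at least 2 gray levels")
  offset <- as.integer(offset)
  if (length(offset) != 2L || all(offset == 0L))
    stop("invalid argument: offset must be a nonzero (row, col) pair")
  q <- if (quantized) {
    if (any(img < 0 | img >= levels)) stop("invalid argument: values outside 0..G-1")
    matrix(as.integer(img), nrow(img), ncol(img))
  } else {
    quantize_gray(img, levels, range)
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(q)))
      stop("invalid argument: mask shape must equal image shape")
  } else {
    mask <- matrix(TRUE, nrow(q), ncol(q))
  }
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  rlo <- max(1L, 1L - dr); rhi <- min(nr, nr - dr)
  clo <- max(1L, 1L - dc); chi <- min(nc, nc - dc)
  if (rlo > rhi || clo > chi)
    stop("degenerate input: offset larger than the image")
  r1 <- rlo:rhi
  c1 <- clo:chi
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok))
    stop("degenerate input: no valid pixel pairs under this offset/mask")
  idx <- a[ok] * levels + b[ok]  # 0-based (i, j) -> i*G + j
  counts <- matrix(tabulate(idx + 1L, nbins = levels^2),
                   levels, levels, byrow = TRUE)
  n_pairs <- sum(ok)
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  structure(list(p = p, levels = levels, offset = offset,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

check_glcm <- function(g) {
  if (!inherits(g, "glcm")) {
    if (is.matrix(g) && nrow(g) == ncol(g))
      g <- structure(list(p = g, levels = nrow(g), offset = c(0L, 1L),
                          symmetric = NA, n_pairs = NA_integer_),
                     class = "glcm")
    else stop("contract violation: not a GLCM")
  }
  if (any(g$p < 0) || abs(sum(g$p) - 1) > 1e-8)
    stop("contract violation: GLCM probabilities must be >= 0 and sum to 1")
  g
}

#' GLCM texture statistics
#'
#' `glcm_entropy()` is `-sum p log p` (0 log 0 := 0), `glcm_energy()` is
#' `sum p^2`, and `glcm_homogeneity()` is `sum p / (1 + (i - j)^2)`. The
#' entropy logarithm defaults to the natural log (nats).
#'
#' @param g A `glcm` (or a bare probability matrix).
#' @param base Log base for entropy: `"natural"`, `"2"` or `"10"`.
#' @return A single numeric value.
#' @export
glcm_entropy <- function(g, base = c("natural", "2", "10")) {
  base <- match.arg(base)
  p <- check_glcm(g)$p
  p <- p[p > 0]
  h <- -sum(p * log(p))
  switch(base, natural = h, "2" = h / log(2), "10" = h / log(10))
}

#' @rdname glcm_entropy
#' @export
glcm_energy <- function(g) {
  p <- check_glcm(g)$p
  sum(p^2)
}

#' @rdname glcm_entropy
#' @export
glcm_homogeneity <- function(g) {
  g <- check_glcm(g)
  p <- g$p
  G <- g$levels
  i <- matrix(seq_len(G), G, G)          # row index
  j <- matrix(seq_len(G), G, G, byrow = TRUE)
  sum(p / (1 + (i - j)^2))
}

#' Extract the texture feature vector of an image
#'
#' Quantizes, builds one GLCM (optionally restricted to a mask and/or
#' averaged over the four standard directions), and returns the three
#' texture statistics.
#'
#' @inheritParams compute_glcm
#' @param average_directions Average the GLCM over offsets (0,1), (1,0),
#'   (1,1), (1,-1) before computing statistics.
#' @param base Entropy log base.
#' @return Named numeric vector `entropy`, `energy`, `homogeneity`.
#' @export
extract_texture_features <- function(img, mask = NULL, levels = 8,
                                     offset = c(0, 1), symmetric = TRUE,
                                     average_directions = FALSE,
                                     base = "natural",
                                     range = attr(img, "range") %||% c(0, 255)) {
  offsets <- if (average_directions)
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1)) else list(offset)
  ps <- lapply(offsets, function(o)
    compute_glcm(img, levels = levels, offset = o, symmetric = symmetric,
                 mask = mask, range = range)$p)
  p <- Reduce(`+`, ps) / length(ps)
  g <- structure(list(p = p, levels = levels, offset = offsets[[1]],
                      symmetric = symmetric, n_pairs = NA_integer_),
                 class = "glcm")
  c(entropy = glcm_entropy(g, base = base),
    energy = glcm_energy(g),
    homogeneity = glcm_homogeneity(g))
}
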