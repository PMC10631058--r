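# Synthetic leaf images with a controllable texture-severity gradient.
#
# The generator draws Gaussian white noise, smooths it with a Gaussian
# filter whose width grows with stress severity, renormalizes, and scales
# it by an amplitude that shrinks with severity. Stronger stress thus
# yields smoother, lower-contrast leaf surfaces: GLCM entropy falls while
# energy and local homogeneity rise, emulating the loss of surface
# complexity seen in stressed leaves.

#' Simulate a leaf image
#'
#' @param width,height Image size in pixels (both >= 16).
#' @param severity Stress severity in `[0, 3]`. Higher severity increases
#'   the texture correlation length by `sigma_per_severity` and shrinks
#'   the gray amplitude by a factor `1 - amplitude_decay * severity / 3`.
#' @param granularity Base correlation length (Gaussian smoothing sigma,
#'   pixels) at severity 0. `granularity = 0` with `amplitude = 0` gives a
#'   constant mid-gray image.
#' @param sigma_per_severity Added smoothing sigma per severity unit.
#' @param amplitude Gray-level standard deviation of the texture at
#'   severity 0 (0 yields a constant image).
#' @param amplitude_decay Fraction of amplitude lost at severity 3.
#' @param leaf_shape If TRUE, the texture fills an elliptical "leaf" on a
#'   dark background (for segmentation tests); otherwise the full frame.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   image.
#' @return Gray image matrix (values in 0..255, attribute `range`).
#' @export
#' @examples
#' img <- simulate_leaf_image(32, 32, severity = 2, seed = 1)
#' range(img)
simulate_leaf_image <- function(width = 64, height = 64, severity = 0,
                                granularity = 0.6, sigma_per_severity = 0.8,
                                amplitude = 55, amplitude_decay = 0.55,
                                leaf_shape = FALSE, seed = NULL) {
  if (width < 16 || height < 16)
    stop("invalid spec: image must be at least 16 x 16")
  if (severity < 0 || severity > 3)
    stop("invalid spec: severity must lie in [0, 3]")
  if (amplitude < 0) stop("invalid spec: amplitude must be >= 0")

  mid <- 128
  img <- with_seed(seed, {
    z <- matrix(rnorm(height * width), height, width)
    sig <- granularity + sigma_per_severity * severity
    if (sig > 0) z <- gaussian_blur(z, sig)
    s <- stats::sd(as.vector(z))
    if (s > 0) z <- z / s
    amp <- amplitude * (1 - amplitude_decay * severity / 3)
    mid + amp * z
  })
  img <- round(pmin(pmax(img, 0), 255))

  if (leaf_shape) {
    cy <- (height + 1) / 2; cx <- (width + 1) / 2
    ry <- height * 0.38; rx <- width * 0.28
    yy <- matrix(seq_len(height), height, width)
    xx <- matrix(seq_len(width), height, width, byrow = TRUE)
    inside <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
    bg <- matrix(12, height, width)
    # keep the leaf bright so edges are strong
    img <- ifelse(inside, pmax(img, 60), bg)
  }
  gray_image(img, range = c(0, 255))
}
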