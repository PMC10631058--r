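# Leaf segmentation: Canny edges, morphological closing, interior fill,
# largest connected component.

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double-threshold hysteresis (weak
#' edges are kept only when connected to a strong edge).
#'
#' @param img Gray matrix.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return Logical edge matrix.
#' @export
canny_edges <- function(img, sigma = 1.4, low = 0.08, high = 0.2) {
  img <- unclass(img)
  if (nrow(img) < 8 || ncol(img) < 8)
    stop("invalid argument: image smaller than the smoothing kernel")
  sm <- gaussian_blur(img, sigma)
  gr <- sobel_gradients(sm)
  mag <- gr$mag
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))

  # non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 0/45/90/135 degrees
  ang <- atan2(gr$gy, gr$gx)           # radians
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  n1 <- mag; n2 <- mag
  pick <- function(dr, dc) shift_mat(mag, dr, dc)
  n1 <- ifelse(sector == 0, pick(0, 1),
        ifelse(sector == 1, pick(1, 1),
        ifelse(sector == 2, pick(1, 0), pick(1, -1))))
  n2 <- ifelse(sector == 0, pick(0, -1),
        ifelse(sector == 1, pick(-1, -1),
        ifelse(sector == 2, pick(-1, 0), pick(-1, 1))))
  keep <- mag >= n1 & mag >= n2

  strong <- keep & mag >= high * mmax
  weak <- keep & mag >= low * mmax
  # hysteresis: grow strong edges through weak pixels to fixpoint
  repeat {
    grown <- weak & dilate3(strong)
    new_strong <- strong | grown
    if (all(new_strong == strong)) break
    strong <- new_strong
  }
  strong
}

#' Segment the leaf in a gray image
#'
#' Detects Canny edges, closes them morphologically, marks everything
#' reachable from the image border without crossing an edge as
#' background, and returns the largest remaining interior region (plus
#' its edge band) as the leaf mask. When no interior region is found a
#' warning is issued and a full-frame mask (attribute `empty = TRUE`) is
#' returned so downstream GLCM computation falls back to the whole image.
#'
#' @inheritParams canny_edges
#' @return Logical mask, TRUE = leaf pixel.
#' @export
#' @examples
#' img <- simulate_leaf_image(48, 48, leaf_shape = TRUE, seed = 1)
#' mask <- segment_leaf(img)
#' mean(mask)
segment_leaf <- function(img, sigma = 1.4, low = 0.08, high = 0.2) {
  edges <- morph_close(canny_edges(img, sigma = sigma, low = low, high = high))
  nr <- nrow(edges); nc <- ncol(edges)
  open_space <- !edges
  # background = components of non-edge space touching the border;
  # foreground = everything else (enclosed regions plus the edges
  # themselves, so internal texture edges stay part of the leaf)
  lab <- connected_components(open_space)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  border_labels <- border_labels[border_labels > 0L]
  foreground <- !(open_space & matrix(lab %in% border_labels, nr, nc))
  if (!any(foreground) || all(foreground)) {
    warning("empty mask: no closed foreground region found; using full frame")
    return(structure(matrix(TRUE, nr, nc), empty = TRUE))
  }
  mask <- largest_component(foreground)
  structure(mask, empty = FALSE)
}
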