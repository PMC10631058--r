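# Linear stress-response model used by the synthetic-data generator.
# Each feature value is
#   baseline + drought_slope*w + salinity_slope*s + interaction*w*s
#            + time_slope*(t-1) + N(0, noise_sd)
# with w, s the integer severity levels and t the sampling time point.

#' Construct a feature response model
#'
#' A response model gives, for every feature, the parameters of the linear
#' predictor used by [simulate_features()] plus a direction tag recording
#' how the feature is expected to move under stress (`"increasing"`,
#' `"decreasing"`, or `"mixed"` for features whose drought and salinity
#' responses have opposite signs).
#'
#' @param params Data frame with columns `feature`, `baseline`,
#'   `drought_slope`, `salinity_slope`, `interaction`, `time_slope`,
#'   `noise_sd`, `direction`.
#' @return An object of class `response_model` (a validated data frame).
#' @seealso [default_response_model()] for the stock parameterization.
#' @export
response_model <- function(params) {
  need <- c("feature", "baseline", "drought_slope", "salinity_slope",
            "interaction", "time_slope", "noise_sd", "direction")
  if (!is.data.frame(params) || !all(need %in% names(params)))
    stop("configuration error: response model needs columns ",
         paste(setdiff(need, names(params)), collapse = ", "))
  params <- as.data.frame(params)[, need]
  if (anyDuplicated(params$feature))
    stop("configuration error: duplicated feature in response model")
  if (any(!is.finite(params$noise_sd)) || any(params$noise_sd < 0))
    stop("configuration error: noise_sd must be finite and >= 0")
  bad <- !params$direction %in% c("increasing", "decreasing", "mixed")
  if (any(bad))
    stop("configuration error: unknown direction for feature(s) ",
         paste(params$feature[bad], collapse = ", "))
  # direction tag must agree with the slope signs (mixed is exempt)
  for (i in seq_len(nrow(params))) {
    dr <- params$direction[i]
    if (dr == "mixed") next
    sgn <- if (dr == "increasing") 1 else -1
    sl <- c(params$drought_slope[i], params$salinity_slope[i])
    if (any(sgn * sl < 0))
      stop("configuration error: slopes of '", params$feature[i],
           "' contradict its direction '", dr, "'")
  }
  rownames(params) <- params$feature
  class(params) <- c("response_model", "data.frame")
  params
}

#' Stock stress-response model
#'
#' The package default emulating the qualitative findings of the cucumber
#' salt/drought experiment: image entropy falls and energy/homogeneity
#' rise under stress; relative water content and chlorophyll index fall
#' while catalase, anthocyanins, phenols and proline rise; the four
#' miRNAs respond strongly and stress-type-specifically, with miR477b
#' carrying the largest absolute slopes and miR399g nearly none. The
#' magnitudes are plausible placeholders chosen once, not calibrated to
#' any measured dataset; only the directions and the relative
#' informativeness of the three feature families are meaningful.
#'
#' @return A `response_model` for the 13 canonical features.
#' @export
#' @examples
#' m <- default_response_model()
#' m["miR477b", ]
default_response_model <- function() {
  tab <- rbind(
    # feature       base   dW     dS     inter  time    sd    direction
    c("entropy",     2.0, -0.15, -0.15,  0,    -0.02,  0.15, "decreasing"),
    c("energy",      0.20, 0.02,  0.02,  0,    -0.002, 0.02, "increasing"),
    c("homogeneity", 0.55, 0.03,  0.03,  0,     0,     0.03, "increasing"),
    c("RWC",        90,   -6,    -4,     0,     0,     4,    "decreasing"),
    c("CI",         35,   -2,    -3,     0,     0.3,   2,    "decreasing"),
    c("CA",         10,    2.5,   1.2,   0,     0,     1.2,  "increasing"),
    c("AC",          5,    0.8,   1.3,   0,     0,     0.8,  "increasing"),
    c("PhC",        12,    1.5,   2.0,   0,     0,     1.5,  "increasing"),
    c("PC",          8,    2.0,   1.0,   0,     0,     1.3,  "increasing"),
    c("miR156a",    10,    1.6,   1.0,   0,     0,     1.1,  "increasing"),
    c("miR166i",     8,   -1.0,   1.6,   0,     0,     1.1,  "mixed"),
    c("miR399g",     6,    0.3,   0.2,   0,     0,     0.6,  "increasing"),
    c("miR477b",    12,    4.0,  -3.0,   0,     0,     0.35, "mixed")
  )
  params <- data.frame(
    feature = tab[, 1],
    baseline = as.numeric(tab[, 2]),
    drought_slope = as.numeric(tab[, 3]),
    salinity_slope = as.numeric(tab[, 4]),
    interaction = as.numeric(tab[, 5]),
    time_slope = as.numeric(tab[, 6]),
    noise_sd = as.numeric(tab[, 7]),
    direction = tab[, 8],
    stringsAsFactors = FALSE
  )
  response_model(params)
}

#' Read / write a response model as YAML
#'
#' The on-disk schema is a mapping `features: {<name>: {baseline, drought_slope,
#' salinity_slope, interaction, time_slope, noise_sd, direction}}`.
#'
#' @param path File path.
#' @return `read_response_model()` returns a `response_model`;
#'   `write_response_model()` returns `path` invisibly.
#' @export
read_response_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$features))
    stop("configuration error: YAML model must have a top-level 'features' map")
  rows <- lapply(names(doc$features), function(f) {
    p <- doc$features[[f]]
    data.frame(feature = f,
               baseline = as.numeric(p$baseline %||% 0),
               drought_slope = as.numeric(p$drought_slope %||% 0),
               salinity_slope = as.numeric(p$salinity_slope %||% 0),
               interaction = as.numeric(p$interaction %||% 0),
               time_slope = as.numeric(p$time_slope %||% 0),
               noise_sd = as.numeric(p$noise_sd %||% 1),
               direction = as.character(p$direction %||% "mixed"),
               stringsAsFactors = FALSE)
  })
  response_model(do.call(rbind, rows))
}

#' @rdname read_response_model
#' @param model A `response_model`.
#' @export
write_response_model <- function(model, path) {
  stopifnot(inherits(model, "response_model"))
  feats <- lapply(seq_len(nrow(model)), function(i) {
    as.list(model[i, c("baseline", "drought_slope", "salinity_slope",
                       "interaction", "time_slope", "noise_sd", "direction")])
  })
  names(feats) <- model$feature
  yaml::write_yaml(list(features = feats), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
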