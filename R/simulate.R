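# Synthetic feature tables: the stand-in for the greenhouse dataset.

#' Simulate a stress-experiment feature table
#'
#' Draws one realization of the experiment described by `design` under the
#' linear response `model`. Each feature value is the model's linear
#' predictor in the drought severity `w`, salinity severity `s`, their
#' product, and the sampling time point, plus independent Gaussian noise.
#' Regeneration with the same `(design, model, seed)` is bit-identical.
#'
#' @param design A [stress_design()].
#' @param model A [response_model()]; must define every requested feature.
#' @param seed Integer seed (NULL uses, and advances, the global RNG).
#' @param features Which features to generate; defaults to the 13
#'   canonical features, all of which the model must define. Pass
#'   `model$feature` to generate a custom model's own features.
#' @return A `feature_table`: data frame with columns `pot_id`,
#'   `replicate`, `time_point`, `drought_level`, `salinity_level`, the
#'   integer severities `drought` and `salinity`, and one column per
#'   feature.
#' @export
#' @examples
#' tab <- simulate_features(stress_design(), seed = 42)
#' dim(tab)  # 240 x (7 + 13)
simulate_features <- function(design, model = default_response_model(),
                              seed = NULL, features = feature_names()) {
  stopifnot(inherits(design, "stress_design"))
  if (!inherits(model, "response_model")) model <- response_model(model)
  missing <- setdiff(features, model$feature)
  if (length(missing))
    stop("configuration error: response model lacks feature(s) ",
         paste(missing, collapse = ", "))

  rec <- design$records
  n <- nrow(rec)
  vals <- with_seed(seed, {
    out <- matrix(NA_real_, n, length(features),
                  dimnames = list(NULL, features))
    for (f in features) {
      p <- model[f, ]
      mu <- p$baseline +
        p$drought_slope * rec$drought +
        p$salinity_slope * rec$salinity +
        p$interaction * rec$drought * rec$salinity +
        p$time_slope * (rec$time_point - 1L)
      eps <- if (p$noise_sd > 0) rnorm(n, 0, p$noise_sd) else 0
      out[, f] <- mu + eps
    }
    out
  })

  tab <- cbind(rec[, c("pot_id", "replicate", "time_point",
                       "drought_level", "drought",
                       "salinity_level", "salinity")],
               as.data.frame(vals))
  feature_table(tab, features = features)
}

#' Construct / validate a feature table
#'
#' A `feature_table` is the in-memory form of the experiment dataset: one
#' row per pot and sampling date carrying the treatment labels, integer
#' severities, and the measured features.
#'
#' @param df Data frame with columns `pot_id`, `replicate`, `time_point`,
#'   `drought_level`, `drought`, `salinity_level`, `salinity`, plus one
#'   numeric column per feature.
#' @param features Character vector naming the feature columns.
#' @return `df` with class `feature_table` and attribute `features`.
#' @export
feature_table <- function(df, features = intersect(feature_names(), names(df))) {
  meta <- c("pot_id", "replicate", "time_point",
            "drought_level", "drought", "salinity_level", "salinity")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  if (!length(features))
    stop("schema error: no feature columns")
  miss <- setdiff(features, names(df))
  if (length(miss))
    stop("schema error: missing feature column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(features))
    stop("schema error: duplicated feature names")
  if (!all(df$drought %in% 0:3) || !all(df$salinity %in% 0:3))
    stop("value error: severity levels must lie in 0..3")
  for (f in features)
    if (!is.numeric(df[[f]]))
      stop("schema error: feature column '", f, "' is not numeric")
  df <- as.data.frame(df)[, c(meta, features)]
  structure(df, features = features,
            class = c("feature_table", "data.frame"))
}

#' @export
print.feature_table <- function(x, ...) {
  feats <- attr(x, "features")
  cat(sprintf("Feature table: %d records, %d features\n", nrow(x), length(feats)))
  cat("  features:", paste(feats, collapse = " "), "\n")
  NextMethod()
}

# subsetting drops to data.frame semantics but keeps the class when the
# schema survives
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    feats <- intersect(attr(x, "features"), names(out))
    ok <- length(feats) > 0 &&
      all(c("pot_id", "drought", "salinity") %in% names(out))
    if (ok) {
      attr(out, "features") <- feats
      class(out) <- c("feature_table", "data.frame")
    } else {
      class(out) <- "data.frame"
      attr(out, "features") <- NULL
    }
  }
  out
}
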