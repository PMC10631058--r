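# Banzhaf power-index feature importance.
#
# Features are players in a cooperative game whose characteristic
# function v(C) is the cross-validated R-squared of the model restricted
# to the coalition C. A feature's raw Banzhaf index is its average
# marginal contribution v(C u {i}) - v(C) over all coalitions C not
# containing i; shares are the raw indices floored at zero and rescaled
# to percentages.

# memoize v over coalitions (key: sorted feature names)
coalition_cache <- function(v) {
  cache <- new.env(parent = emptyenv())
  count <- new.env(parent = emptyenv()); count$n <- 0L
  f <- function(members) {
    key <- paste0("k:", paste(sort(members), collapse = "|"))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    count$n <- count$n + 1L
    val <- v(members)
    cache[[key]] <- val
    val
  }
  list(v = f, count = count)
}

banzhaf_result <- function(tab, meta) {
  structure(list(table = tab, meta = meta), class = "banzhaf_result")
}

#' @export
print.banzhaf_result <- function(x, ...) {
  cat(sprintf("Banzhaf importance (%s, %d features, %s)\n",
              x$meta$estimator, nrow(x$table),
              x$meta$group %||% "unnamed group"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Exact Banzhaf power index
#'
#' Evaluates the characteristic function on all `2^n` coalitions (each
#' exactly once, via a cache) and computes every feature's mean marginal
#' contribution. Raw indices may be negative; percentage shares floor
#' negatives at zero (see [normalize_shares()]).
#'
#' @param features Character vector of player/feature names (n <= 15).
#' @param v `function(members)` returning the coalition's value;
#'   `v(character(0))` must be defined.
#' @param meta Optional metadata list.
#' @return Object of class `banzhaf_result` whose `table` has columns
#'   `feature`, `raw`, `share`, `se` (NA for the exact engine).
#' @export
#' @examples
#' v <- function(m) sum(c(a = 1, b = 2, c = 3)[m])
#' banzhaf_exact(c("a", "b", "c"), v)$table
banzhaf_exact <- function(features, v, meta = list()) {
  n <- length(features)
  if (n < 1) stop("invalid game: no features")
  if (n > 15)
    stop("group too large for exact enumeration (2^n coalitions); ",
         "use banzhaf_monte_carlo()")
  cv <- coalition_cache(v)
  nC <- 2^n
  vals <- numeric(nC)
  for (m in 0:(nC - 1)) {
    members <- features[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    vals[m + 1] <- cv$v(members)
  }
  raw <- vapply(seq_len(n), function(i) {
    bit <- 2^(i - 1)
    without <- which(bitwAnd(0:(nC - 1), bit) == 0)   # 1-based indices
    mean(vals[without + bit] - vals[without])
  }, numeric(1))
  tab <- data.frame(feature = features, raw = raw,
                    share = normalize_shares(raw), se = NA_real_,
                    stringsAsFactors = FALSE)
  banzhaf_result(tab, modifyList(
    list(estimator = "exact", coalitions = cv$count$n), meta))
}

#' Monte Carlo Banzhaf estimator
#'
#' For each feature, samples coalitions of the remaining features
#' uniformly (each other feature included independently with probability
#' 1/2 — the distribution under which the exact index is the mean) and
#' averages the marginal contributions. Unbiased; reports the standard
#' error of each raw index. Deterministic under `seed`.
#'
#' @inheritParams banzhaf_exact
#' @param n_samples Sampled coalitions per feature.
#' @param seed Integer seed.
#' @return A `banzhaf_result` with standard errors in `se`.
#' @export
banzhaf_monte_carlo <- function(features, v, n_samples = 200, seed = NULL,
                                meta = list()) {
  n <- length(features)
  if (n < 1) stop("invalid game: no features")
  if (n_samples < 1) stop("invalid argument: n_samples >= 1 required")
  cv <- coalition_cache(v)
  est <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      others <- features[-i]
      contrib <- vapply(seq_len(n_samples), function(s) {
        inc <- runif(length(others)) < 0.5
        C <- others[inc]
        cv$v(c(C, features[i])) - cv$v(C)
      }, numeric(1))
      c(mean(contrib),
        if (n_samples > 1) sd(contrib) / sqrt(n_samples) else NA_real_)
    })
  })
  raw <- vapply(est, `[`, numeric(1), 1)
  se <- vapply(est, `[`, numeric(1), 2)
  tab <- data.frame(feature = features, raw = raw,
                    share = normalize_shares(raw), se = se,
                    stringsAsFactors = FALSE)
  banzhaf_result(tab, modifyList(
    list(estimator = "monte_carlo", n_samples = n_samples, seed = seed,
         coalitions = cv$count$n), meta))
}

#' Normalize raw Banzhaf indices to percentage shares
#'
#' Negative raw indices (features that hurt cross-validated performance)
#' are floored at zero, then the vector is rescaled to sum to 100.
#'
#' @param raw Numeric vector of raw indices.
#' @return Numeric vector of shares summing to 100.
#' @export
normalize_shares <- function(raw) {
  floored <- pmax(raw, 0)
  s <- sum(floored)
  if (s <= 0)
    stop("undefined shares: all raw indices are <= 0")
  100 * floored / s
}

#' Cross-validation performance characteristic function
#'
#' Returns the characteristic function used for feature importance:
#' `v(C)` is the pooled cross-validated R-squared of the scenario SVR
#' restricted to the features in C, with the fold assignment fixed once
#' (derived from `seed`) and shared by every coalition so that value
#' differences reflect the features, not resampling noise. `v(empty) =
#' 0`, and coalition evaluation failures also score 0 (with a warning).
#'
#' @inheritParams svm_evaluate
#' @param metric `"r_squared"` (default) or `"neg_mse"`.
#' @return `function(members)` suitable for [banzhaf_exact()] /
#'   [banzhaf_monte_carlo()].
#' @export
performance_characteristic <- function(table, scenario = "combined",
                                       kernel = kernel_spec("gaussian"),
                                       C = 1, epsilon = 0.1, k = 5,
                                       seed = NULL, subset = "unconfounded",
                                       metric = c("r_squared", "neg_mse")) {
  metric <- match.arg(metric)
  rows <- scenario_rows(table, scenario, subset)
  folds <- make_folds(sum(rows), k = k, seed = child_seed(seed, 11))
  function(members) {
    if (length(members) == 0) return(0)
    rep <- tryCatch(
      svm_evaluate(table, scenario, features = members, kernel = kernel,
                   C = C, epsilon = epsilon, folds = folds, subset = subset),
      error = function(e) {
        warning("coalition {", paste(members, collapse = ","),
                "} failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(rep)) return(0)
    if (metric == "r_squared") rep$r_squared else -rep$mse
  }
}
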