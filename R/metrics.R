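# Regression metrics and the k-fold cross-validation protocol.

#' Mean squared error
#'
#' `mean((predicted - observed)^2)`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("contract error: observed and predicted lengths differ")
  if (length(observed) < 1L) stop("contract error: need at least one value")
  mean((predicted - observed)^2)
}

#' Coefficient of determination
#'
#' `1 - SSres / SStot` with `SStot` the total sum of squares about the
#' mean of the observations. Equals 1 for perfect prediction, 0 for
#' predicting the observed mean, and can be negative.
#'
#' @inheritParams mse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("contract error: observed and predicted lengths differ")
  if (length(observed) < 2L) stop("contract error: need n >= 2")
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0)
    stop("undefined denominator: observed values are constant")
  1 - sum((predicted - observed)^2) / sstot
}

#' Assign records to cross-validation folds
#'
#' Balanced random assignment (fold sizes differ by at most one),
#' deterministic under `seed`. When `groups` is supplied, all records of
#' a group share a fold (groups are dealt to folds largest-first onto the
#' currently smallest fold, with ties broken by the seeded shuffle), so
#' repeated measures of one pot never straddle the train/test split.
#'
#' @param n Number of records.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param groups Optional grouping vector of length `n` (e.g. pot ids).
#' @return Integer vector of fold indices in `1..k`.
#' @export
#' @examples
#' table(make_folds(240, 5, seed = 1))
make_folds <- function(n, k = 5, seed = NULL, groups = NULL) {
  if (n < k) stop("invalid folds: n < k")
  if (k < 2) stop("invalid folds: need k >= 2")
  if (is.null(groups)) {
    with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  } else {
    if (length(groups) != n)
      stop("invalid folds: groups length must equal n")
    gs <- table(groups)
    if (length(gs) < k)
      stop("invalid folds: fewer groups than folds")
    ord <- with_seed(seed, {
      gnames <- sample(names(gs))               # seeded tie-break
      gnames[order(-gs[gnames])]
    })
    fold_of <- integer(length(ord)); names(fold_of) <- ord
    sizes <- numeric(k)
    for (g in ord) {
      f <- which.min(sizes)
      fold_of[g] <- f
      sizes[f] <- sizes[f] + gs[[g]]
    }
    unname(fold_of[as.character(groups)])
  }
}

#' Cross-validate a model factory
#'
#' For each fold, fits `fit_fun` on the remaining folds and predicts the
#' held-out records. Per-fold MSE and R-squared are reported together
#' with the aggregate metrics computed in one pass over the pooled
#' out-of-fold predictions (not the mean of per-fold values).
#'
#' @param fit_fun `function(X, y)` returning a fitted object understood
#'   by `predict(object, X)`.
#' @param X Numeric feature matrix (rows = records).
#' @param y Numeric target vector.
#' @param folds Integer fold assignment from [make_folds()].
#' @param meta Optional named list stored in the report.
#' @return Object of class `cv_report`: list with `mse`, `r_squared`,
#'   `per_fold` (data frame), `predictions` (pooled out-of-fold, in input
#'   row order), `observed`, and `meta`.
#' @export
cross_validate <- function(fit_fun, X, y, folds, meta = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n || length(folds) != n)
    stop("contract error: X, y and folds sizes disagree")
  ks <- sort(unique(folds))
  pred <- rep(NA_real_, n)
  per_fold <- data.frame(fold = ks, n = NA_integer_,
                         mse = NA_real_, r_squared = NA_real_)
  for (i in seq_along(ks)) {
    te <- folds == ks[i]
    fit <- tryCatch(fit_fun(X[!te, , drop = FALSE], y[!te]),
                    error = function(e)
                      stop("model training failed in fold ", ks[i], ": ",
                           conditionMessage(e)))
    p <- as.numeric(predict(fit, X[te, , drop = FALSE]))
    pred[te] <- p
    per_fold$n[i] <- sum(te)
    per_fold$mse[i] <- mse(y[te], p)
    per_fold$r_squared[i] <- if (sum(te) >= 2 && var(y[te]) > 0)
      r_squared(y[te], p) else NA_real_
  }
  structure(list(mse = mse(y, pred),
                 r_squared = r_squared(y, pred),
                 per_fold = per_fold,
                 predictions = pred,
                 observed = y,
                 meta = meta),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report\n")
  if (length(x$meta)) {
    m <- x$meta[!vapply(x$meta, is.null, TRUE)]
    cat(" ", paste(names(m), unlist(lapply(m, format)), sep = "=",
                   collapse = "  "), "\n")
  }
  cat(sprintf("  pooled MSE = %.4f   pooled R^2 = %.4f   (k = %d)\n",
              x$mse, x$r_squared, nrow(x$per_fold)))
  invisible(x)
}

#' Serialize a CV report
#'
#' `cv_report_row()` flattens a report to the one-line grid format
#' (kernel x scenario x model -> MSE, R^2); `cv_report_json()` writes the
#' full report as JSON.
#'
#' @param x A `cv_report`.
#' @return A one-row data frame / a JSON string.
#' @export
cv_report_row <- function(x) {
  stopifnot(inherits(x, "cv_report"))
  data.frame(
    group = x$meta$group %||% NA_character_,
    scenario = x$meta$scenario %||% NA_character_,
    kernel = x$meta$kernel %||% NA_character_,
    model = x$meta$model %||% NA_character_,
    mse = x$mse, r_squared = x$r_squared,
    stringsAsFactors = FALSE
  )
}

#' @rdname cv_report_row
#' @export
cv_report_json <- function(x) {
  stopifnot(inherits(x, "cv_report"))
  jsonlite::toJSON(list(mse = x$mse, r_squared = x$r_squared,
                        per_fold = x$per_fold, meta = x$meta),
                   auto_unbox = TRUE, digits = NA)
}
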