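# Epsilon support-vector regression with four kernels and the stress
# scenario target encoding.
#
# The solver minimizes, over beta in [-C, C]^n,
#   0.5 beta' (K + 1) beta - y' beta + epsilon ||beta||_1,
# the dual of epsilon-SVR with the bias absorbed into the kernel (the
# intercept is weakly regularized instead of free, a standard variant
# that removes the equality constraint). Predictions are
# f(x) = sum_i beta_i (k(x, x_i) + 1).

#' Specify an SVM kernel
#'
#' Kernels: linear `x . x'`, polynomial `(gamma x . x' + coef0)^degree`,
#' gaussian `exp(-gamma ||x - x'||^2)`, sigmoid `tanh(gamma x . x' +
#' coef0)`. `gamma = NULL` defers to the fit-time default `1/d` with `d`
#' the number of features.
#'
#' @param kind One of `"linear"`, `"polynomial"`, `"gaussian"`,
#'   `"sigmoid"`.
#' @param gamma Positive kernel parameter (ignored by the linear kernel).
#' @param degree Polynomial degree (>= 2).
#' @param coef0 Additive constant for polynomial/sigmoid kernels.
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "linear", "polynomial", "sigmoid"),
                        gamma = NULL, degree = 3, coef0 = 0) {
  kind <- match.arg(kind)
  if (!is.null(gamma) && (!is.numeric(gamma) || gamma <= 0))
    stop("invalid kernel: gamma must be positive")
  if (degree < 2) stop("invalid kernel: degree must be >= 2")
  structure(list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

#' Kernel matrix
#'
#' @param spec A [kernel_spec()].
#' @param X,Y Numeric matrices with matching column count (`Y` defaults
#'   to `X`).
#' @return `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("invalid kernel input: dimension mismatch")
  g <- spec$gamma %||% (1 / max(1L, ncol(X)))
  switch(spec$kind,
    linear = X %*% t(Y),
    polynomial = (g * (X %*% t(Y)) + spec$coef0)^spec$degree,
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * (X %*% t(Y))
      exp(-g * pmax(d2, 0))
    },
    sigmoid = tanh(g * (X %*% t(Y)) + spec$coef0)
  )
}

#' Fit epsilon support-vector regression
#'
#' Features are z-standardized with the training data's own statistics
#' (stored in the model and reapplied at prediction time; constant
#' columns get unit scale).
#'
#' @param X Numeric feature matrix (rows = samples); column names, when
#'   present, are stored so prediction is invariant to feature order.
#' @param y Numeric target vector with at least two distinct values.
#' @param kernel A [kernel_spec()].
#' @param C Box constraint (regularization), default 1.
#' @param epsilon Width of the insensitive tube, default 0.1.
#' @param tol,max_sweeps Coordinate-descent stopping controls.
#' @return Object of class `svr_model`.
#' @export
#' @examples
#' x <- matrix(seq(0, 3, length.out = 40))
#' m <- svr_fit(x, 2 * x[, 1], kernel_spec("linear"), C = 10)
#' predict(m, matrix(c(1, 2)))
svr_fit <- function(X, y, kernel = kernel_spec("gaussian"), C = 1,
                    epsilon = 0.1, tol = 1e-6, max_sweeps = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("training error: X rows != length(y)")
  if (length(unique(y)) < 2)
    stop("training error: degenerate targets (fewer than 2 distinct values)")
  if (C <= 0 || epsilon < 0) stop("training error: need C > 0, epsilon >= 0")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  spec <- kernel
  if (is.null(spec$gamma) && spec$kind != "linear")
    spec$gamma <- 1 / ncol(Xs)
  K <- kernel_matrix(spec, Xs) + 1  # +1 absorbs the bias
  sol <- svr_cd(K, y, C, epsilon, tol, as.integer(max_sweeps))
  structure(list(beta = as.numeric(sol$beta),
                 X = Xs, center = center, scale = scale,
                 feature_names = colnames(X),
                 kernel = spec, C = C, epsilon = epsilon,
                 sweeps = sol$sweeps, converged = sol$converged),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  fn <- object$feature_names
  if (!is.null(fn) && !is.null(colnames(newdata))) {
    miss <- setdiff(fn, colnames(newdata))
    if (length(miss))
      stop("prediction error: missing feature(s) ", paste(miss, collapse = ", "))
    newdata <- newdata[, fn, drop = FALSE]
  }
  if (ncol(newdata) != length(object$center))
    stop("prediction error: wrong feature dimension")
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  Kn <- kernel_matrix(object$kernel, Xs, object$X) + 1
  as.numeric(Kn %*% object$beta)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("epsilon-SVR: %s kernel%s, C = %g, epsilon = %g, n = %d, SV = %d\n",
              x$kernel$kind,
              if (x$kernel$kind == "linear") ""
              else sprintf(" (gamma = %.4g)", x$kernel$gamma),
              x$C, x$epsilon, nrow(x$X), sum(x$beta != 0)))
  invisible(x)
}

# Scenario encoding ------------------------------------------------------

#' Encode the prediction target for a stress scenario
#'
#' Drought predicts the drought severity `w`, salinity predicts `s`, and
#' the combined scenario predicts both jointly (two outputs evaluated
#' together).
#'
#' @param scenario `"drought"`, `"salinity"` or `"combined"`.
#' @param w,s Integer severities in 0..3.
#' @return Numeric vector (drought/salinity) or a 2-column matrix
#'   (`w`, `s`) for the combined scenario.
#' @export
encode_target <- function(scenario = c("drought", "salinity", "combined"),
                          w, s) {
  scenario <- match.arg(scenario)
  if (any(!(w %in% 0:3)) || any(!(s %in% 0:3)))
    stop("config error: severities must lie in 0..3")
  switch(scenario,
         drought = as.numeric(w),
         salinity = as.numeric(s),
         combined = cbind(w = as.numeric(w), s = as.numeric(s)))
}

#' Select the rows a scenario is evaluated on
#'
#' The drought scenario uses only unsalinized pots (`s = 0`) so severity
#' prediction is unconfounded by the other stress; symmetrically the
#' salinity scenario uses `w = 0`. The combined scenario uses all rows.
#' `subset = "all"` keeps every row for the single-stress scenarios too.
#'
#' @param table A [feature_table()].
#' @param scenario Scenario name.
#' @param subset `"unconfounded"` (default) or `"all"`.
#' @return Logical row selector.
#' @export
scenario_rows <- function(table, scenario = c("drought", "salinity", "combined"),
                          subset = c("unconfounded", "all")) {
  scenario <- match.arg(scenario)
  subset <- match.arg(subset)
  if (scenario == "combined" || subset == "all")
    return(rep(TRUE, nrow(table)))
  if (scenario == "drought") table$salinity == 0 else table$drought == 0
}

#' Cross-validated evaluation of an SVR on a stress scenario
#'
#' Builds the feature matrix and target(s) for the scenario, fits one
#' epsilon-SVR per output on each training fold, and pools all
#' out-of-fold residuals (both outputs concatenated in the combined
#' scenario) into aggregate MSE/R-squared.
#'
#' @param table A [feature_table()].
#' @param scenario Scenario name.
#' @param features Feature columns to use (default all in the table).
#' @param kernel A [kernel_spec()].
#' @param C,epsilon SVR constants.
#' @param k Number of CV folds.
#' @param seed Fold seed.
#' @param folds Optional precomputed fold assignment (overrides
#'   `k`/`seed`); must match the scenario's row count.
#' @param subset Row-subsetting rule, see [scenario_rows()].
#' @param group_by_pot Assign whole pots to folds (off by default).
#' @param meta Extra metadata stored in the report.
#' @return A `cv_report`.
#' @export
svm_evaluate <- function(table, scenario = "combined",
                         features = attr(table, "features"),
                         kernel = kernel_spec("gaussian"),
                         C = 1, epsilon = 0.1, k = 5, seed = NULL,
                         folds = NULL, subset = "unconfounded",
                         group_by_pot = FALSE, meta = list()) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(features, attr(table, "features"))
  if (length(miss))
    stop("config error: unknown feature(s) ", paste(miss, collapse = ", "))
  rows <- scenario_rows(table, scenario, subset)
  dat <- as.data.frame(table)[rows, , drop = FALSE]
  X <- as.matrix(dat[, features, drop = FALSE])
  Y <- encode_target(scenario, dat$drought, dat$salinity)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  n <- nrow(X)
  if (is.null(folds)) {
    folds <- make_folds(n, k = k, seed = seed,
                        groups = if (group_by_pot) dat$pot_id else NULL)
  } else if (length(folds) != n) {
    stop("config error: folds length does not match scenario rows")
  }

  ks <- sort(unique(folds))
  pred <- matrix(NA_real_, n, ncol(Y))
  for (f in ks) {
    te <- folds == f
    for (j in seq_len(ncol(Y))) {
      fit <- svr_fit(X[!te, , drop = FALSE], Y[!te, j], kernel = kernel,
                     C = C, epsilon = epsilon)
      pred[te, j] <- predict(fit, X[te, , drop = FALSE])
    }
  }
  obs_pool <- as.vector(Y)
  pred_pool <- as.vector(pred)
  per_fold <- do.call(rbind, lapply(ks, function(f) {
    te <- folds == f
    o <- as.vector(Y[te, , drop = FALSE]); p <- as.vector(pred[te, , drop = FALSE])
    data.frame(fold = f, n = sum(te), mse = mse(o, p),
               r_squared = if (var(o) > 0) r_squared(o, p) else NA_real_)
  }))
  structure(list(mse = mse(obs_pool, pred_pool),
                 r_squared = r_squared(obs_pool, pred_pool),
                 per_fold = per_fold,
                 predictions = pred,
                 observed = Y,
                 folds = folds,
                 meta = modifyList(list(scenario = scenario,
                                        kernel = kernel$kind,
                                        gamma = kernel$gamma, C = C,
                                        n = n, seed = seed), meta)),
            class = "cv_report")
}
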