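# Real-coded genetic algorithm and particle swarm optimization, used to
# tune the SVM kernel parameter. Both work on a bounded box; dimensions
# declared log-scaled are optimized in log10 space.

#' Define a box search space
#'
#' @param lower,upper Numeric bounds per dimension (`lower < upper`).
#' @param scale `"linear"` or `"log"` per dimension; log-scaled
#'   dimensions require positive bounds and are searched in log10 space.
#' @param names Optional parameter names.
#' @return Object of class `search_space`.
#' @export
search_space <- function(lower, upper, scale = "linear", names = NULL) {
  d <- length(lower)
  if (length(upper) != d) stop("invalid space: bound lengths differ")
  scale <- rep(scale, length.out = d)
  if (any(lower >= upper)) stop("invalid space: lower must be < upper")
  if (any(scale == "log" & lower <= 0))
    stop("invalid space: log scale requires positive bounds")
  if (!all(scale %in% c("linear", "log")))
    stop("invalid space: scale must be 'linear' or 'log'")
  structure(list(lower = lower, upper = upper, scale = scale,
                 names = names), class = "search_space")
}

space_to_internal <- function(space, x) {
  ifelse(space$scale == "log", log10(x), x)
}
space_from_internal <- function(space, z) {
  ifelse(space$scale == "log", 10^z, z)
}
space_bounds_internal <- function(space) {
  list(lower = space_to_internal(space, space$lower),
       upper = space_to_internal(space, space$upper))
}

#' Optimizer configurations
#'
#' `ga_config()` defaults follow the published tuning setup: 500
#' generations, population 100, crossover fraction 0.5. Unstated GA
#' details default to tournament selection (size 2), BLX-0.5 blend
#' crossover, Gaussian mutation (rate 0.1, sd = 10% of range) and
#' elitism 1. `pso_config()` defaults likewise: 100 iterations, 200
#' particles, inertia 1, cognitive acceleration 1; the unstated social
#' acceleration defaults to 1 and velocities are clamped to 20% of the
#' range per dimension.
#'
#' @param max_iterations,population_size Budget.
#' @param crossover_fraction Fraction of each generation produced by
#'   crossover.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd_frac Mutation sd as a fraction of the (internal)
#'   range.
#' @param elitism Number of best individuals copied unchanged.
#' @param seed Integer seed.
#' @return A config list.
#' @export
ga_config <- function(max_iterations = 500, population_size = 100,
                      crossover_fraction = 0.5, mutation_rate = 0.1,
                      mutation_sd_frac = 0.1, elitism = 1, seed = NULL) {
  if (population_size < 2) stop("invalid config: population must be >= 2")
  if (crossover_fraction < 0 || crossover_fraction > 1)
    stop("invalid config: crossover_fraction must lie in [0, 1]")
  list(max_iterations = max_iterations, population_size = population_size,
       crossover_fraction = crossover_fraction, mutation_rate = mutation_rate,
       mutation_sd_frac = mutation_sd_frac, elitism = elitism, seed = seed)
}

#' @rdname ga_config
#' @param inertia,cognitive,social PSO acceleration constants.
#' @param velocity_clamp Max |velocity| as a fraction of the range.
#' @export
pso_config <- function(max_iterations = 100, population_size = 200,
                       inertia = 1, cognitive = 1, social = 1,
                       velocity_clamp = 0.2, seed = NULL) {
  if (population_size < 2) stop("invalid config: population must be >= 2")
  if (inertia < 0) stop("invalid config: inertia must be >= 0")
  list(max_iterations = max_iterations, population_size = population_size,
       inertia = inertia, cognitive = cognitive, social = social,
       velocity_clamp = velocity_clamp, seed = seed)
}

# wrap an objective: non-finite values are flagged and penalized
safe_objective <- function(fn) {
  evals <- new.env(parent = emptyenv()); evals$n <- 0L
  f <- function(x) {
    evals$n <- evals$n + 1L
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  list(fn = f, evals = evals)
}

optim_result <- function(par, value, trace, n_evals, method) {
  structure(list(par = par, value = value, trace = trace,
                 n_evals = n_evals, method = method),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("%s: best value %.6g at (%s) after %d evaluations\n",
              x$method, x$value,
              paste(signif(x$par, 6), collapse = ", "), x$n_evals))
  invisible(x)
}

#' Minimize with a real-coded genetic algorithm
#'
#' Tournament selection, BLX-alpha blend crossover on a fixed fraction of
#' each generation, Gaussian mutation, and elitism, on the (internally
#' log-transformed) box. Candidates with non-finite objective values are
#' discarded via an infinite penalty. Deterministic under `config$seed`.
#'
#' @param fn Objective `function(x)` returning a scalar to minimize.
#' @param space A [search_space()].
#' @param config A [ga_config()].
#' @param init Optional matrix (rows = candidates, natural scale) seeded
#'   into the initial population.
#' @return An `optim_result`: best parameters (natural scale), best
#'   value, per-iteration best-so-far `trace` (length iterations + 1,
#'   non-increasing), and `n_evals`.
#' @export
#' @examples
#' r <- ga_minimize(function(x) (x - 2)^2, search_space(0, 10),
#'                  ga_config(50, 30, seed = 1))
#' r$par
ga_minimize <- function(fn, space, config = ga_config(), init = NULL) {
  so <- safe_objective(fn)
  b <- space_bounds_internal(space)
  d <- length(b$lower)
  rng <- b$upper - b$lower
  np <- config$population_size
  eval_pop <- function(P)
    apply(P, 1, function(z) so$fn(space_from_internal(space, z)))

  with_seed(config$seed, {
    P <- matrix(runif(np * d, rep(b$lower, each = np), rep(b$upper, each = np)),
                np, d)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      ni <- min(nrow(init), np)
      Z <- t(apply(init[seq_len(ni), , drop = FALSE], 1,
                   function(x) space_to_internal(space, x)))
      Z <- matrix(Z, ncol = d)
      P[seq_len(ni), ] <- pmin(pmax(Z, rep(b$lower, each = ni)),
                               rep(b$upper, each = ni))
    }
    fit <- eval_pop(P)
    best_val <- min(fit)
    best_par <- P[which.min(fit), ]
    trace <- best_val
    tournament <- function() {
      i <- sample.int(np, 2)
      if (fit[i[1]] <= fit[i[2]]) i[1] else i[2]
    }
    for (it in seq_len(config$max_iterations)) {
      ord <- order(fit)
      n_el <- min(config$elitism, np)
      newP <- matrix(NA_real_, np, d)
      if (n_el > 0) newP[seq_len(n_el), ] <- P[ord[seq_len(n_el)], , drop = FALSE]
      n_cross <- min(np - n_el, round(config$crossover_fraction * np))
      row <- n_el
      alpha <- 0.5
      while (row < n_el + n_cross) {
        p1 <- P[tournament(), ]; p2 <- P[tournament(), ]
        lo <- pmin(p1, p2); hi <- pmax(p1, p2); span <- hi - lo
        child <- runif(d, lo - alpha * span, hi + alpha * span)
        row <- row + 1
        newP[row, ] <- child
      }
      while (row < np) {        # rest: selected copies (mutation follows)
        row <- row + 1
        newP[row, ] <- P[tournament(), ]
      }
      if (np > n_el) {
        idx <- (n_el + 1):np
        mut <- matrix(runif(length(idx) * d) < config$mutation_rate,
                      length(idx), d)
        noise <- matrix(rnorm(length(idx) * d,
                              sd = rep(config$mutation_sd_frac * rng,
                                       each = length(idx))),
                        length(idx), d)
        newP[idx, ] <- newP[idx, , drop = FALSE] + mut * noise
      }
      newP <- pmin(pmax(newP, rep(b$lower, each = np)), rep(b$upper, each = np))
      P <- newP
      fit <- eval_pop(P)
      if (min(fit) < best_val) {
        best_val <- min(fit)
        best_par <- P[which.min(fit), ]
      }
      trace <- c(trace, best_val)
    }
    optim_result(par = space_from_internal(space, best_par),
                 value = best_val, trace = trace,
                 n_evals = so$evals$n, method = "GA")
  })
}

#' Minimize with particle swarm optimization
#'
#' Canonical velocity update `v <- w v + c1 r1 (pbest - x) + c2 r2
#' (gbest - x)` with per-dimension velocity clamping and box clipping,
#' on the internally log-transformed space. Deterministic under
#' `config$seed`.
#'
#' @inheritParams ga_minimize
#' @param config A [pso_config()].
#' @return An `optim_result` (see [ga_minimize()]).
#' @export
pso_minimize <- function(fn, space, config = pso_config(), init = NULL) {
  so <- safe_objective(fn)
  b <- space_bounds_internal(space)
  d <- length(b$lower)
  rng <- b$upper - b$lower
  np <- config$population_size
  vmax <- config$velocity_clamp * rng
  eval_pop <- function(P)
    apply(P, 1, function(z) so$fn(space_from_internal(space, z)))

  with_seed(config$seed, {
    X <- matrix(runif(np * d, rep(b$lower, each = np), rep(b$upper, each = np)),
                np, d)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      ni <- min(nrow(init), np)
      Z <- t(apply(init[seq_len(ni), , drop = FALSE], 1,
                   function(x) space_to_internal(space, x)))
      Z <- matrix(Z, ncol = d)
      X[seq_len(ni), ] <- pmin(pmax(Z, rep(b$lower, each = ni)),
                               rep(b$upper, each = ni))
    }
    V <- matrix(0, np, d)
    fit <- eval_pop(X)
    pbest <- X; pbest_val <- fit
    gi <- which.min(fit)
    gbest <- X[gi, ]; gbest_val <- fit[gi]
    trace <- gbest_val
    for (it in seq_len(config$max_iterations)) {
      r1 <- matrix(runif(np * d), np, d)
      r2 <- matrix(runif(np * d), np, d)
      V <- config$inertia * V +
        config$cognitive * r1 * (pbest - X) +
        config$social * r2 * sweep(-X, 2, gbest, "+")
      V <- pmin(pmax(V, rep(-vmax, each = np)), rep(vmax, each = np))
      X <- pmin(pmax(X + V, rep(b$lower, each = np)), rep(b$upper, each = np))
      fit <- eval_pop(X)
      imp <- fit < pbest_val
      pbest[imp, ] <- X[imp, , drop = FALSE]
      pbest_val[imp] <- fit[imp]
      gi <- which.min(pbest_val)
      if (pbest_val[gi] < gbest_val) {
        gbest_val <- pbest_val[gi]; gbest <- pbest[gi, ]
      }
      trace <- c(trace, gbest_val)
    }
    optim_result(par = space_from_internal(space, gbest),
                 value = gbest_val, trace = trace,
                 n_evals = so$evals$n, method = "PSO")
  })
}

# Objective cache keyed by parameters rounded to 6 significant digits,
# so optimizers do not refit numerically identical candidates.
cached_objective <- function(fn) {
  cache <- new.env(parent = emptyenv())
  hits <- new.env(parent = emptyenv()); hits$n <- 0L
  f <- function(x) {
    key <- paste(signif(x, 6), collapse = "|")
    if (!is.null(cache[[key]])) {
      hits$n <- hits$n + 1L
      return(cache[[key]])
    }
    v <- fn(x)
    cache[[key]] <- v
    v
  }
  list(fn = f, hits = hits, cache = cache)
}

#' Tune the SVM kernel parameter for a stress scenario
#'
#' The objective is the pooled cross-validation MSE of the scenario SVR
#' at a candidate kernel parameter gamma (for the linear kernel, which
#' has no gamma, the box constraint C is tuned instead), on folds that
#' are fixed once and shared by every candidate. The default parameter is
#' seeded into the initial population, so the tuned objective can never
#' exceed the untuned one. `optimizer = "none"` evaluates the default
#' parameter only.
#'
#' @inheritParams svm_evaluate
#' @param kernel_kind Kernel name.
#' @param optimizer `"ga"`, `"pso"` or `"none"`.
#' @param config Optimizer config ([ga_config()] / [pso_config()]);
#'   ignored for `"none"`.
#' @param gamma_space,C_space Search spaces (log-scaled by default:
#'   gamma in `[1e-4, 1e2]`, C in `[1e-3, 1e3]`).
#' @return List with the tuning `result` (`optim_result` or NULL), the
#'   final `report` (`cv_report` at the tuned parameter), the tuned
#'   `kernel`, and `C`.
#' @export
tune_svm <- function(table, scenario = "combined",
                     features = attr(table, "features"),
                     kernel_kind = "gaussian",
                     optimizer = c("none", "ga", "pso"),
                     config = NULL, k = 5, seed = NULL,
                     C = 1, epsilon = 0.1, subset = "unconfounded",
                     gamma_space = search_space(1e-4, 1e2, "log", "gamma"),
                     C_space = search_space(1e-3, 1e3, "log", "C"),
                     meta = list()) {
  optimizer <- match.arg(optimizer)
  rows <- scenario_rows(table, scenario, subset)
  n <- sum(rows)
  folds <- make_folds(n, k = k, seed = child_seed(seed, 1))
  tunes_C <- kernel_kind == "linear"
  default_par <- if (tunes_C) C else 1 / length(features)
  space <- if (tunes_C) C_space else gamma_space

  eval_at <- function(par) {
    kern <- if (tunes_C) kernel_spec("linear")
            else kernel_spec(kernel_kind, gamma = par)
    svm_evaluate(table, scenario, features = features, kernel = kern,
                 C = if (tunes_C) par else C, epsilon = epsilon,
                 folds = folds, subset = subset,
                 meta = modifyList(meta, list(optimizer = optimizer)))
  }

  if (optimizer == "none") {
    rep0 <- eval_at(default_par)
    return(list(result = NULL, report = rep0,
                kernel = rep0$meta$kernel, par = default_par, C = C))
  }

  co <- cached_objective(function(par) eval_at(par)$mse)
  if (is.null(config))
    config <- if (optimizer == "ga") ga_config(seed = child_seed(seed, 2))
              else pso_config(seed = child_seed(seed, 2))
  if (is.null(config$seed)) config$seed <- child_seed(seed, 2)
  init <- matrix(default_par, 1, 1)
  res <- if (optimizer == "ga")
    ga_minimize(co$fn, space, config = config, init = init)
  else
    pso_minimize(co$fn, space, config = config, init = init)
  final <- eval_at(res$par)
  final$meta$tuned_par <- res$par
  final$meta$cache_hits <- co$hits$n
  list(result = res, report = final, kernel = kernel_kind,
       par = res$par, C = if (tunes_C) res$par else C)
}
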