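# Orchestration: the full evaluation grid (feature group x scenario x
# kernel x model), Banzhaf importance runs, and the feature ablation.

#' Run the full evaluation grid
#'
#' One cross-validated (MSE, R-squared) result per combination of
#' feature group, stress scenario, kernel, and model (`SVM` = default
#' parameter, `SVM-GA` / `SVM-PSO` = kernel parameter tuned by the
#' respective optimizer). The default 3 x 3 x 4 x 3 grid has 108 cells.
#' Cell failures are recorded in the `status` column and the grid
#' continues. With `out_dir` set, finished cells are written to disk as
#' `cell_<group>_<scenario>_<kernel>_<model>.csv` and skipped on re-run.
#'
#' @param table A [feature_table()].
#' @param groups Named list of feature sets (default [feature_groups()]).
#' @param scenarios Scenario names.
#' @param kernels Kernel names.
#' @param models Subset of `c("SVM", "SVM-GA", "SVM-PSO")`.
#' @param seed Top-level seed fixing folds and optimizers.
#' @param ga,pso Optimizer configs. The defaults here are scaled-down
#'   budgets (25 x 16 GA, 25 x 24 PSO) so a full grid completes in
#'   minutes; pass `ga_config()` / `pso_config()` for the full published
#'   budgets.
#' @param k Number of CV folds.
#' @param subset Scenario row-subsetting rule, see [scenario_rows()].
#' @param out_dir Optional directory for resumable per-cell results.
#' @return Data frame with one row per grid cell: `group`, `scenario`,
#'   `kernel`, `model`, `mse`, `r_squared`, `tuned_par`, `status`.
#' @export
run_grid <- function(table, groups = feature_groups(),
                     scenarios = c("drought", "salinity", "combined"),
                     kernels = c("linear", "polynomial", "gaussian", "sigmoid"),
                     models = c("SVM", "SVM-GA", "SVM-PSO"),
                     seed = NULL,
                     ga = ga_config(max_iterations = 25, population_size = 16),
                     pso = pso_config(max_iterations = 25, population_size = 24),
                     k = 5, subset = "unconfounded", out_dir = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(names(groups))) stop("config error: groups must be named")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  cells <- expand.grid(group = names(groups), scenario = scenarios,
                       kernel = kernels, model = models,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$group, cells$scenario, cells$kernel,
                       cells$model), , drop = FALSE]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    fname <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("cell_%s_%s_%s_%s.csv", cell$group,
                                 cell$scenario, cell$kernel, cell$model))
    if (!is.null(out_dir) && file.exists(fname)) {
      out[[i]] <- utils::read.csv(fname, stringsAsFactors = FALSE)
      next
    }
    # every cell gets its own deterministic seed derived from the
    # top-level seed and its grid position
    cseed <- child_seed(seed, i)
    optimizer <- switch(cell$model, "SVM" = "none", "SVM-GA" = "ga",
                        "SVM-PSO" = "pso")
    config <- switch(cell$model, "SVM" = NULL, "SVM-GA" = ga, "SVM-PSO" = pso)
    row <- tryCatch({
      fit <- tune_svm(table, scenario = cell$scenario,
                      features = groups[[cell$group]],
                      kernel_kind = cell$kernel, optimizer = optimizer,
                      config = config, k = k, seed = cseed, subset = subset,
                      meta = list(group = cell$group, model = cell$model))
      data.frame(cell, mse = fit$report$mse,
                 r_squared = fit$report$r_squared,
                 tuned_par = if (is.null(fit$result)) NA_real_ else fit$par,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cell, mse = NA_real_, r_squared = NA_real_,
                 tuned_par = NA_real_,
                 status = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    if (!is.null(out_dir)) utils::write.csv(row, fname, row.names = FALSE)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Banzhaf importance for a feature group
#'
#' Delegates to the exact or Monte Carlo Banzhaf engine with a
#' cross-validation R-squared characteristic function whose folds are
#' fixed by `seed` across all coalitions.
#'
#' @inheritParams run_grid
#' @param group `"morphological"`, `"physiological"`, `"miRNA"` or
#'   `"all"` (all 13 features).
#' @param scenario Scenario the characteristic function is computed on.
#' @param estimator `"exact"` (default, feasible up to 15 features) or
#'   `"monte_carlo"`.
#' @param n_samples Monte Carlo samples per feature.
#' @param kernel Kernel used by the characteristic function.
#' @return A `banzhaf_result`.
#' @export
run_importance <- function(table, group = "miRNA", scenario = "combined",
                           estimator = c("exact", "monte_carlo"),
                           n_samples = 200, seed = NULL,
                           kernel = kernel_spec("gaussian"), k = 5,
                           subset = "unconfounded") {
  estimator <- match.arg(estimator)
  fg <- feature_groups()
  feats <- if (identical(group, "all")) unlist(fg, use.names = FALSE)
           else fg[[group]]
  if (is.null(feats))
    stop("config error: unknown group '", group, "'")
  feats <- intersect(feats, attr(table, "features"))
  if (!length(feats)) stop("config error: group features absent from table")
  v <- performance_characteristic(table, scenario = scenario, kernel = kernel,
                                  k = k, seed = seed, subset = subset)
  meta <- list(group = group, scenario = scenario, seed = seed)
  if (estimator == "exact") banzhaf_exact(feats, v, meta = meta)
  else banzhaf_monte_carlo(feats, v, n_samples = n_samples,
                           seed = child_seed(seed, 21), meta = meta)
}

#' Feature ablation
#'
#' Re-evaluates the configured model with `drop` removed from `features`
#' and reports it next to the full-feature run (same folds, same
#' optimizer seeds), plus the R-squared change `delta_r_squared =
#' reduced - full`.
#'
#' @inheritParams run_grid
#' @param drop Features to remove.
#' @param features Full feature set to ablate from.
#' @param scenario Scenario name.
#' @param kernel_kind Kernel name.
#' @param model `"SVM"`, `"SVM-GA"` or `"SVM-PSO"`.
#' @param config Optimizer config for the tuned models.
#' @return List with `full` and `reduced` (`cv_report`s) and
#'   `delta_r_squared`.
#' @export
run_ablation <- function(table, drop, features = feature_groups()$miRNA,
                         scenario = "combined", kernel_kind = "linear",
                         model = "SVM-GA",
                         config = ga_config(max_iterations = 25,
                                            population_size = 16),
                         seed = NULL, k = 5, subset = "unconfounded") {
  miss <- setdiff(drop, features)
  if (length(miss))
    stop("config error: cannot drop absent feature(s) ",
         paste(miss, collapse = ", "))
  kept <- setdiff(features, drop)
  if (!length(kept))
    stop("config error: ablation would drop all features")
  optimizer <- switch(model, "SVM" = "none", "SVM-GA" = "ga",
                      "SVM-PSO" = "pso",
                      stop("config error: unknown model '", model, "'"))
  if (optimizer == "none") config <- NULL
  run1 <- function(feats) {
    tune_svm(table, scenario = scenario, features = feats,
             kernel_kind = kernel_kind, optimizer = optimizer,
             config = config, k = k, seed = seed, subset = subset,
             meta = list(model = model))$report
  }
  full <- run1(features)
  reduced <- run1(kept)
  list(full = full, reduced = reduced,
       delta_r_squared = reduced$r_squared - full$r_squared,
       dropped = drop)
}
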