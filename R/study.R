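model_names <- c("lasso", "en", "ssl", "ssl_iar", "ssen", "ssen_iar")

#' Typical deviance-selected scale pairs for the lattice scenarios
#'
#' (spike, slab) scale pairs for the spike-and-slab models under the two
#' lattice simulation conditions, as selected by deviance-minimizing grid
#' search over `s0` in 0.01..0.1 and `s1` in \{1, 2\} in this design.
#' Supplying them as `fixed_hyperparams` in [study_config()] skips the grid
#' search, which is how reduced-replicate studies keep their runtime
#' proportionate.
#'
#' @param signal_value 0.10 (large effect) or 0.05 (small effect).
#' @return A named list of `c(s0, s1)` pairs for `ssl`, `ssl_iar`, `ssen`,
#'   `ssen_iar`.
#' @export
default_study_hyperparams <- function(signal_value = 0.10) {
  if (isTRUE(all.equal(signal_value, 0.10))) {
    list(ssl = c(0.08, 1), ssl_iar = c(0.10, 1),
         ssen = c(0.07, 1), ssen_iar = c(0.10, 2))
  } else if (isTRUE(all.equal(signal_value, 0.05))) {
    list(ssl = c(0.06, 1), ssl_iar = c(0.09, 1),
         ssen = c(0.05, 1), ssen_iar = c(0.10, 2))
  } else {
    rlang::abort("No stored hyperparameters for this signal value; use the grid.")
  }
}

#' Configuration of a simulation study
#'
#' Bundles everything that determines a multi-model simulation study:
#' the generating scenario, the number of replicate datasets, the models
#' to fit, the hyperparameter grids (or fixed per-model scale pairs that
#' skip grid search), the CV layout, and a master seed from which all
#' per-dataset seeds are derived.
#'
#' @param scenario A [sim_scenario].
#' @param n_datasets Number of replicate datasets (default 50, a
#'   desk-scale setting; see the methods vignette for the Monte Carlo
#'   error this implies).
#' @param models Character vector from `lasso`, `en`, `ssl`, `ssl_iar`,
#'   `ssen`, `ssen_iar`.
#' @param s0_grid,s1_grid Grids for the spike-and-slab scale search
#'   (defaults `seq(0.01, 0.1, 0.01)` and `c(1, 2)`).
#' @param k Folds (default 5).
#' @param repeats CV repeats per dataset (default 1).
#' @param fixed_hyperparams Optional named list of `c(s0, s1)` per
#'   spike-and-slab model, e.g. [default_study_hyperparams()]; models
#'   listed here skip the grid search. Traditional models always select
#'   their penalty on a lambda path.
#' @param master_seed Integer master seed.
#' @param control A [fit_control()].
#' @return A list of class `study_config`.
#' @export
study_config <- function(scenario = sim_scenario(), n_datasets = 50,
                         models = model_names,
                         s0_grid = seq(0.01, 0.1, by = 0.01),
                         s1_grid = c(1, 2), k = 5, repeats = 1,
                         fixed_hyperparams = NULL, master_seed = 1,
                         control = fit_control()) {
  stopifnot(inherits(scenario, "sim_scenario"), n_datasets >= 1)
  models <- gsub("-", "_", tolower(models))
  bad <- setdiff(models, model_names)
  if (length(bad) > 0L) {
    rlang::abort(paste0("Unknown model(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(scenario = scenario, n_datasets = as.integer(n_datasets),
                 models = models, s0_grid = s0_grid, s1_grid = s1_grid,
                 k = as.integer(k), repeats = as.integer(repeats),
                 fixed_hyperparams = fixed_hyperparams,
                 master_seed = as.integer(master_seed), control = control),
            class = "study_config")
}

# Traditional lasso/EN: penalty chosen on a glmnet lambda path by CV
# deviance, with the same stratified folds as the spike-and-slab models;
# metrics come from the prevalidated held-out predictions at the chosen
# lambda. Returns a one-row tibble.
cv_traditional_path <- function(X, y, xi, foldid, threshold = 0.5) {
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = xi,
                             foldid = foldid, type.measure = "deviance",
                             keep = TRUE, standardize = TRUE)
  i <- which.min(cvfit$cvm)
  eta <- cvfit$fit.preval[, i]
  p_hat <- stats::plogis(eta) # prevalidated values are on the link scale
  dplyr::bind_cols(tibble::tibble(s0 = cvfit$lambda[i], s1 = cvfit$lambda[i]),
                   all_metrics(y, p_hat, threshold))
}

# one model on one dataset -> one-row tibble (s0, s1, metrics)
study_fit_one <- function(model, X, y, graph, config, folds, seed_cv) {
  if (model %in% c("lasso", "en")) {
    xi <- if (model == "lasso") 1 else 0.5
    return(cv_traditional_path(X, y, xi, foldid = folds[, 1L]))
  }
  fixed <- config$fixed_hyperparams[[model]]
  g <- if (grepl("_iar$", model)) graph else NULL
  if (!is.null(fixed)) {
    prior <- ss_prior(model, s0 = fixed[1L], s1 = fixed[2L])
    cv <- kfold_cv_impl(X, y, prior, g, config$k, config$repeats,
                        seed_cv, config$control, folds = folds)
    dplyr::bind_cols(tibble::tibble(s0 = fixed[1L], s1 = fixed[2L]),
                     cv$summary)
  } else {
    prior <- ss_prior(model, s0 = min(config$s0_grid), s1 = max(config$s1_grid))
    gs <- grid_select_impl(X, y, prior, g, config$s0_grid, config$s1_grid,
                           config$k, config$repeats, seed_cv, config$control)
    gs$best
  }
}

#' Run a multi-model simulation study
#'
#' Generates `n_datasets` replicate datasets from the configured scenario
#' and, for each dataset and model, selects hyperparameters (fixed pair or
#' deviance-minimizing grid search; traditional models search a lambda
#' path) and records the cross-validated prediction-error and
#' classification metrics at the selected point. Fold assignments are
#' shared across models within a dataset so model comparisons are paired.
#' Replicate failures are caught, counted, and reported — never silently
#' dropped.
#'
#' @param config A [study_config()].
#' @return An object of class `ssen_study`: `per_dataset` (one row per
#'   dataset x model), `aggregate` (per-model means over datasets, missing
#'   metrics excluded with counts), `failures`, and the config.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  scen <- config$scenario
  graph <- if (any(grepl("_iar$", config$models))) {
    lattice_adjacency(scen$n_rows, scen$n_cols, "rook")
  } else NULL
  seeds <- withr::with_seed(config$master_seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2L * config$n_datasets),
           ncol = 2L))
  rows <- vector("list", config$n_datasets)
  failures <- list()
  for (d in seq_len(config$n_datasets)) {
    ds <- generate_dataset(scen, seed = seeds[d, 1L])
    folds <- make_folds(ds$y, config$k, seeds[d, 2L], config$repeats)
    for (model in config$models) {
      res <- tryCatch(
        study_fit_one(model, ds$X, ds$y, graph, config, folds, seeds[d, 2L]),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(dataset = d, seed = seeds[d, 1L], model = model,
                         message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(dataset = d, seed = seeds[d, 1L], model = model),
          res)
      }
    }
  }
  per_dataset <- dplyr::bind_rows(rows)
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(dataset = integer(), seed = integer(),
                   model = character(), message = character())
  if (nrow(failures) > 0L) {
    rlang::warn(paste0(nrow(failures), " replicate fit(s) failed and were excluded."))
  }
  metric_cols <- setdiff(names(per_dataset),
                         c("dataset", "seed", "model", "s0", "s1"))
  means <- per_dataset |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_datasets = dplyr::n(),
      s0 = mean(.data$s0), s1 = mean(.data$s1),
      dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE)))
  missing <- per_dataset |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   ~ sum(is.na(.x)),
                                   .names = "n_missing_{.col}"))
  aggregate <- dplyr::left_join(means, missing, by = "model") |>
    dplyr::arrange(match(.data$model, model_names))
  structure(list(per_dataset = per_dataset, aggregate = aggregate,
                 failures = failures, config = config),
            class = "ssen_study")
}

#' @export
print.ssen_study <- function(x, ...) {
  cat("<ssen_study> ", x$config$n_datasets, " replicate dataset(s), ",
      length(x$config$models), " model(s)\n", sep = "")
  print(dplyr::select(x$aggregate, "model", "s0", "s1", "deviance", "auc",
                      "mse", "mae", "mc", "ac", "sn", "sp", "ppv", "npv",
                      "mcc", "f1"))
  invisible(x)
}

#' @rdname run_study
#' @param x An `ssen_study` object.
#' @param ... Unused.
#' @export
tidy.ssen_study <- function(x, ...) x$per_dataset

#' @rdname run_study
#' @export
glance.ssen_study <- function(x, ...) x$aggregate

# metrics where smaller is better
.ascending_metrics <- c("deviance", "mse", "mae", "mc")

#' Rank models on one aggregate metric
#'
#' Direction-aware ranking of the study's models: deviance, MSE, MAE and
#' misclassification rank ascending (smaller is better), all other metrics
#' descending. Ties are broken by model name for a stable order.
#'
#' @param study An `ssen_study` from [run_study()].
#' @param metric Name of an aggregate metric column (e.g. `"auc"`,
#'   `"mcc"`).
#' @return A tibble with `model`, the metric value, and `rank` (1 = best),
#'   ordered best first.
#' @export
compare_models <- function(study, metric) {
  stopifnot(inherits(study, "ssen_study"))
  agg <- study$aggregate
  if (!metric %in% names(agg)) {
    rlang::abort(paste0("Unknown metric '", metric, "'."))
  }
  value <- agg[[metric]]
  ord <- if (metric %in% .ascending_metrics) {
    order(value, agg$model)
  } else {
    order(-value, agg$model)
  }
  tibble::tibble(model = agg$model[ord], value = value[ord],
                 rank = seq_along(ord))
}

#' Read a feature table from delimited text
#'
#' Reads a delimited file with a header row holding numeric feature
#' columns and one label column, validates that no values are missing and
#' that the label is binary after optional mapping, and reports the sample
#' size, feature count and class balance.
#'
#' @param path Path to the file (delimiter is guessed from the extension:
#'   `.csv` comma, `.tsv` tab, otherwise whitespace).
#' @param label Name of the label column.
#' @param label_map Optional named vector mapping label values to 0/1,
#'   e.g. `c(CN = 0, Dementia = 1)`.
#' @return A tibble of numeric features plus an integer 0/1 label column.
#' @export
load_feature_table <- function(path, label, label_map = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
               csv = readr::read_csv(path, show_col_types = FALSE),
               tsv = readr::read_tsv(path, show_col_types = FALSE),
               readr::read_table(path, show_col_types = FALSE))
  if (nrow(df) == 0L) rlang::abort("The feature table is empty.")
  if (!label %in% names(df)) {
    rlang::abort(paste0("Label column '", label, "' not found."))
  }
  if (anyNA(df)) {
    cells <- which(is.na(df), arr.ind = TRUE)
    msg <- paste(utils::head(
      paste0("row ", cells[, 1L], ", column '", names(df)[cells[, 2L]], "'"),
      10), collapse = "; ")
    rlang::abort(paste0("Missing values at: ", msg))
  }
  lab <- df[[label]]
  if (!is.null(label_map)) {
    unmapped <- setdiff(unique(as.character(lab)), names(label_map))
    if (length(unmapped) > 0L) {
      rlang::abort(paste0("Unmapped label value(s): ",
                          paste(unmapped, collapse = ", ")))
    }
    lab <- unname(label_map[as.character(lab)])
  }
  if (!all(lab %in% c(0, 1))) {
    rlang::abort("Label column must be binary 0/1 (after mapping).")
  }
  feats <- df[setdiff(names(df), label)]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    rlang::abort("All feature columns must be numeric.")
  }
  out <- feats
  out[[label]] <- as.integer(lab)
  rlang::inform(sprintf(
    "Loaded %d subjects x %d features; %d (%.1f%%) in class 1.",
    nrow(out), ncol(feats), sum(lab == 1), 100 * mean(lab == 1)))
  tibble::as_tibble(out)
}
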