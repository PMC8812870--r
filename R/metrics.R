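#' Total binomial deviance
#'
#' \eqn{-2 \sum_i [y_i \log \hat p_i + (1-y_i)\log(1-\hat p_i)]}, summed
#' over subjects (a total, not a mean); predicted probabilities are clipped
#' away from 0 and 1.
#'
#' @param y Binary 0/1 outcomes.
#' @param p_hat Predicted probabilities.
#' @param clip Clipping bound (default 1e-10).
#' @return A non-negative number.
#' @export
#' @examples
#' binomial_deviance(c(0, 1, 0, 1), rep(0.5, 4)) # 8 log 2
binomial_deviance <- function(y, p_hat, clip = 1e-10) {
  if (length(y) != length(p_hat)) {
    rlang::abort("`y` and `p_hat` must have equal length.")
  }
  p <- pmin(pmax(p_hat, clip), 1 - clip)
  -2 * sum(y * log(p) + (1 - y) * log1p(-p))
}

# Mann-Whitney AUC with ties counted 1/2; NA when a class is absent.
auc_rank <- function(y, p_hat) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p_hat, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prediction-error metrics for predicted probabilities
#'
#' Returns the total deviance, AUC (Mann-Whitney with ties counted 1/2),
#' mean squared error, mean absolute error, and misclassification
#' \eqn{\frac1N \sum_i I(|y_i - \hat p_i| > 0.5)} — note the strict
#' inequality, so a predicted probability of exactly 0.5 never counts as
#' misclassified. AUC is `NA` when only one class is present.
#'
#' @inheritParams binomial_deviance
#' @return A one-row tibble with columns `deviance`, `auc`, `mse`, `mae`,
#'   `mc`.
#' @export
#' @examples
#' prediction_error_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
prediction_error_metrics <- function(y, p_hat) {
  if (length(y) != length(p_hat)) {
    rlang::abort("`y` and `p_hat` must have equal length.")
  }
  tibble::tibble(
    deviance = binomial_deviance(y, p_hat),
    auc = auc_rank(y, p_hat),
    mse = mean((y - p_hat)^2),
    mae = mean(abs(y - p_hat)),
    mc = mean(abs(y - p_hat) > 0.5)
  )
}

#' Threshold predicted probabilities into class labels
#'
#' Assigns label 1 when the probability strictly exceeds the threshold.
#'
#' @param p_hat Predicted probabilities.
#' @param threshold Threshold in the open interval (0, 1); default 0.5.
#' @return An integer vector of 0/1 labels.
#' @export
#' @examples
#' classify(c(0.49, 0.5, 0.51)) # 0 0 1
classify <- function(p_hat, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must be a single number strictly inside (0, 1).")
  }
  as.integer(p_hat > threshold)
}

#' Confusion-matrix counts
#'
#' Either tabulates observed versus predicted labels, or wraps counts given
#' directly.
#'
#' @param y Observed 0/1 labels (or omit and give counts).
#' @param y_hat Predicted 0/1 labels.
#' @param tp,fp,tn,fn Counts, when constructing directly.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(y = NULL, y_hat = NULL,
                             tp = NULL, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.null(y)) {
    if (length(y) != length(y_hat)) {
      rlang::abort("`y` and `y_hat` must have equal length.")
    }
    tp <- sum(y == 1 & y_hat == 1)
    fp <- sum(y == 0 & y_hat == 1)
    tn <- sum(y == 0 & y_hat == 0)
    fn <- sum(y == 1 & y_hat == 0)
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0)) {
    rlang::abort("Confusion counts must be non-negative.")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP =", x$tp, " FP =", x$fp,
      " TN =", x$tn, " FN =", x$fn, "\n")
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, positive/negative predictive value,
#' Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' and F1 score \eqn{F1 = 2 TP / (2 TP + FP + FN)}. Any metric with a zero
#' denominator is reported as `NA` (for MCC, when any of the four factors
#' is zero).
#'
#' @param counts A [confusion_counts] object.
#' @return A one-row tibble with columns `ac`, `sn`, `sp`, `ppv`, `npv`,
#'   `mcc`, `f1`.
#' @export
#' @examples
#' confusion_metrics(confusion_counts(tp = 30, fp = 4, tn = 230, fn = 9))
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total <= 0) rlang::abort("At least one scored subject is required.")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  fac <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(fac == 0)) NA_real_ else {
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(fac)))
  }
  tibble::tibble(
    ac = (tp + tn) / total,
    sn = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    mcc = mcc,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
}

# all twelve metrics (prediction error + classification) from pooled
# predictions; used by CV and the study harness
all_metrics <- function(y, p_hat, threshold = 0.5) {
  pe <- prediction_error_metrics(y, p_hat)
  cm <- confusion_metrics(confusion_counts(y, classify(p_hat, threshold)))
  dplyr::bind_cols(pe, cm)
}

# Stratified fold assignment: within each outcome class, a seeded shuffle
# assigns fold labels 1..k cyclically. Returns an N x repeats integer
# matrix. Errors when a class has fewer members than k.
make_folds <- function(y, k, seed, repeats = 1) {
  if (k < 2) rlang::abort("`k` must be at least 2.")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < k)) {
    rlang::abort(paste0(
      "Each outcome class must have at least k members (smallest class: ",
      min(counts), "); choose a smaller k."))
  }
  n <- length(y)
  withr::with_seed(seed, {
    folds <- matrix(NA_integer_, n, repeats)
    for (r in seq_len(repeats)) {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        folds[idx, r] <- rep_len(seq_len(k), length(idx))
      }
    }
    folds
  })
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits subjects into `k` outcome-stratified folds by a seeded shuffle,
#' fits the model on each training set and predicts the held-out fold, so
#' each subject receives exactly one held-out prediction per repeat.
#' Prediction-error and classification metrics are computed on the pooled
#' held-out predictions of each repeat, then averaged over repeats.
#'
#' @inheritParams fit_ssen
#' @param k Number of folds (default 5).
#' @param repeats Number of independent repetitions of the whole CV
#'   (default 1; 10 gives more stable estimates on small samples).
#' @param seed Integer seed controlling the fold shuffles.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `ssen_cv`: a list with `predictions` (tibble
#'   of per-subject held-out predictions: `repeat_id`, `fold`, `row`, `y`,
#'   `p_hat`), `metrics` (one row per repeat), and `summary` (one row,
#'   averaged over repeats).
#' @export
kfold_cv <- function(data, label = "y", prior, graph = NULL, k = 5,
                     repeats = 1, seed = 1, control = fit_control(),
                     threshold = 0.5) {
  xy <- extract_design(data, label)
  kfold_cv_impl(xy$X, xy$y, prior, graph, k, repeats, seed, control,
                threshold)
}

kfold_cv_impl <- function(X, y, prior, graph = NULL, k = 5, repeats = 1,
                          seed = 1, control = fit_control(),
                          threshold = 0.5, folds = NULL) {
  validate_xy(X, y)
  if (is.null(folds)) folds <- make_folds(y, k, seed, repeats)
  preds <- vector("list", repeats * k)
  pos <- 0L
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      test <- which(folds[, r] == f)
      train <- which(folds[, r] != f)
      fit <- fit_ssen_impl(X[train, , drop = FALSE], y[train], prior, graph,
                           control)
      p_hat <- predict(fit, X[test, , drop = FALSE], type = "prob")
      pos <- pos + 1L
      preds[[pos]] <- tibble::tibble(repeat_id = r, fold = f, row = test,
                                     y = y[test], p_hat = p_hat)
    }
  }
  predictions <- dplyr::bind_rows(preds)
  metrics <- predictions |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::group_modify(~ all_metrics(.x$y, .x$p_hat, threshold)) |>
    dplyr::ungroup()
  summary <- metrics |>
    dplyr::summarise(dplyr::across(-"repeat_id", ~ mean(.x, na.rm = TRUE)))
  structure(list(predictions = predictions, metrics = metrics,
                 summary = summary, k = k, repeats = repeats, seed = seed,
                 prior = prior, threshold = threshold),
            class = "ssen_cv")
}

#' @export
print.ssen_cv <- function(x, ...) {
  cat("<ssen_cv> ", x$k, "-fold CV, ", x$repeats, " repeat(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname kfold_cv
#' @param x An `ssen_cv` object.
#' @param ... Unused.
#' @export
tidy.ssen_cv <- function(x, ...) x$metrics

#' @rdname kfold_cv
#' @export
glance.ssen_cv <- function(x, ...) x$summary

#' Deviance-minimizing selection over a (spike, slab) scale grid
#'
#' Evaluates every admissible pair from `s0_grid` x `s1_grid` (pairs with
#' `s0 >= s1` are skipped with a notice) by stratified k-fold
#' cross-validation with identical fold assignments, so grid points are
#' directly comparable. The chosen point minimizes the mean cross-validated
#' deviance; ties are broken by smaller `s0`, then smaller `s1`.
#'
#' @inheritParams kfold_cv
#' @param s0_grid,s1_grid Numeric vectors of candidate spike and slab
#'   scales.
#' @return An object of class `ssen_grid`: `grid` (one row of CV metrics
#'   per admissible pair), `best` (the chosen row), and the shared fold
#'   bookkeeping.
#' @export
grid_select <- function(data, label = "y", prior, graph = NULL,
                        s0_grid, s1_grid, k = 5, repeats = 1, seed = 1,
                        control = fit_control(), threshold = 0.5) {
  xy <- extract_design(data, label)
  grid_select_impl(xy$X, xy$y, prior, graph, s0_grid, s1_grid, k, repeats,
                   seed, control, threshold)
}

grid_select_impl <- function(X, y, prior, graph = NULL, s0_grid, s1_grid,
                             k = 5, repeats = 1, seed = 1,
                             control = fit_control(), threshold = 0.5) {
  stopifnot(inherits(prior, "ss_prior"))
  pairs <- tidyr::expand_grid(s0 = sort(unique(s0_grid)),
                              s1 = sort(unique(s1_grid)))
  n_all <- nrow(pairs)
  pairs <- dplyr::filter(pairs, .data$s0 < .data$s1)
  if (nrow(pairs) == 0L) {
    rlang::abort("No admissible (s0, s1) pairs: all had s0 >= s1.")
  }
  if (nrow(pairs) < n_all) {
    rlang::inform(paste0("Skipped ", n_all - nrow(pairs),
                         " grid point(s) with s0 >= s1."))
  }
  folds <- make_folds(y, k, seed, repeats)
  rows <- purrr::pmap(pairs, function(s0, s1) {
    pr <- ss_prior(s0 = s0, s1 = s1, xi = prior$xi,
                   spike_slab = prior$spike_slab, spatial = prior$spatial,
                   tau = prior$tau, density_form = prior$density_form)
    cv <- kfold_cv_impl(X, y, pr, graph, k, repeats, seed, control,
                        threshold, folds = folds)
    dplyr::bind_cols(tibble::tibble(s0 = s0, s1 = s1), cv$summary)
  })
  grid <- dplyr::bind_rows(rows)
  ranked <- dplyr::arrange(grid, .data$deviance, .data$s0, .data$s1)
  best <- ranked[1L, ]
  structure(list(grid = grid, best = best, k = k, repeats = repeats,
                 seed = seed, prior = prior),
            class = "ssen_grid")
}

#' @export
print.ssen_grid <- function(x, ...) {
  cat("<ssen_grid> ", nrow(x$grid), " grid points; chosen s0 = ",
      x$best$s0, ", s1 = ", x$best$s1,
      " (CV deviance ", round(x$best$deviance, 2), ")\n", sep = "")
  invisible(x)
}

#' @rdname grid_select
#' @param x An `ssen_grid` object.
#' @param ... Unused.
#' @export
tidy.ssen_grid <- function(x, ...) x$grid

#' @rdname grid_select
#' @export
glance.ssen_grid <- function(x, ...) x$best
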