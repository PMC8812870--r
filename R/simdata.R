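#' Simulation scenario for 2-D lattice predictor images
#'
#' Describes one generating condition for the lattice simulation design:
#' subjects carry a spatially correlated Gaussian predictor image on an
#' `n_rows` by `n_cols` lattice, a circular region of locations has
#' non-zero logistic-regression coefficients, and binary outcomes follow a
#' Bernoulli distribution with logit link (no intercept in the generator).
#'
#' The defaults are the large-effect condition: a 40 x 40 lattice (1600
#' predictors), N = 250 subjects, constant predictor mean -1, unit
#' variance, correlation `0.9^d` in Euclidean lattice distance `d`, and a
#' closed disc of radius 4 about the lattice centre — exactly 49 locations
#' (3.06% of 1600) — with coefficients 0.10. The companion small-effect
#' condition uses `signal_value = 0.05` with `predictor_mean = -1.25`.
#' Both produce event rates around 13-14%.
#'
#' @param n_rows,n_cols Lattice dimensions (default 40 x 40).
#' @param n_subjects Number of subjects per dataset (default 250).
#' @param signal_value Coefficient value inside the disc (default 0.10).
#' @param predictor_mean Constant mean of every location (default -1).
#' @param signal_center Lattice coordinate `c(row, col)` of the disc
#'   centre; default the lattice centre `ceiling(dim / 2)`.
#' @param signal_radius Euclidean radius of the non-zero disc (default 4;
#'   on a 40 x 40 lattice the closed disc then holds exactly 49 points).
#' @param rho Correlation decay base: locations at Euclidean distance `d`
#'   have correlation `rho^d` (default 0.90).
#' @return An object of class `sim_scenario`.
#' @export
#' @examples
#' sc <- sim_scenario()
#' sum(build_beta_image(sc) != 0) # 49
sim_scenario <- function(n_rows = 40, n_cols = 40, n_subjects = 250,
                         signal_value = 0.10, predictor_mean = -1,
                         signal_center = NULL, signal_radius = 4,
                         rho = 0.90) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_subjects >= 1,
            signal_radius >= 0, rho > 0, rho < 1)
  if (is.null(signal_center)) {
    signal_center <- c(ceiling(n_rows / 2), ceiling(n_cols / 2))
  }
  r0 <- signal_center[1L]; c0 <- signal_center[2L]
  if (r0 - signal_radius < 1 || r0 + signal_radius > n_rows ||
      c0 - signal_radius < 1 || c0 + signal_radius > n_cols) {
    rlang::abort("The signal disc must fit inside the lattice.")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_subjects = as.integer(n_subjects),
                 signal_value = signal_value,
                 predictor_mean = predictor_mean,
                 signal_center = as.numeric(signal_center),
                 signal_radius = signal_radius, rho = rho),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$n_rows, "x", x$n_cols, " lattice, N = ",
      x$n_subjects, ", signal ", x$signal_value, " on disc r = ",
      x$signal_radius, ", mean ", x$predictor_mean, ", rho = ", x$rho,
      "\n", sep = "")
  invisible(x)
}

# row-major lattice coordinates, node (r, c) -> (r - 1) * n_cols + c
lattice_coords <- function(n_rows, n_cols) {
  cbind(row = rep(seq_len(n_rows), each = n_cols),
        col = rep(seq_len(n_cols), times = n_rows))
}

#' True coefficient image of a scenario
#'
#' `beta_j = signal_value` for lattice points whose squared Euclidean
#' distance to the disc centre is at most `signal_radius^2`, zero
#' elsewhere; vectorized row-major (matching [lattice_adjacency()]).
#'
#' @param scenario A [sim_scenario].
#' @return A numeric coefficient vector of length `n_rows * n_cols`.
#' @export
build_beta_image <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  xy <- lattice_coords(scenario$n_rows, scenario$n_cols)
  d2 <- (xy[, 1L] - scenario$signal_center[1L])^2 +
        (xy[, 2L] - scenario$signal_center[2L])^2
  ifelse(d2 <= scenario$signal_radius^2, scenario$signal_value, 0)
}

# Cholesky factors of the lattice correlation matrix, cached per
# (n_rows, n_cols, rho) because they are expensive relative to sampling.
.chol_cache <- new.env(parent = emptyenv())

scenario_chol <- function(scenario) {
  key <- paste(scenario$n_rows, scenario$n_cols, scenario$rho, sep = "_")
  if (!is.null(.chol_cache[[key]])) return(.chol_cache[[key]])
  xy <- lattice_coords(scenario$n_rows, scenario$n_cols)
  D <- as.matrix(stats::dist(xy))
  R <- tryCatch(chol(scenario$rho^D),
                error = function(e) rlang::abort(
                  "Cholesky factorization of the lattice correlation matrix failed.",
                  parent = e))
  .chol_cache[[key]] <- R
  R
}

#' Simulate spatially correlated predictor images
#'
#' Draws `n` independent subject images from a multivariate normal
#' distribution with constant mean, unit variance, and correlation
#' `rho^d` between locations at Euclidean lattice distance `d`, returned
#' as an `n` by `n_rows * n_cols` matrix of row-major vectorized images.
#'
#' @param scenario A [sim_scenario].
#' @param n Number of subjects (default `scenario$n_subjects`).
#' @param seed Optional integer seed for reproducibility.
#' @return A numeric matrix with one row per subject.
#' @export
simulate_predictors <- function(scenario, n = scenario$n_subjects,
                                seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  R <- scenario_chol(scenario)
  J <- scenario$n_rows * scenario$n_cols
  draw <- function() {
    Z <- matrix(stats::rnorm(n * J), n, J)
    scenario$predictor_mean + Z %*% R
  }
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(X) <- sprintf("x%04d", seq_len(J))
  X
}

#' Simulate binary outcomes from a logistic model
#'
#' `y_i ~ Bernoulli(plogis(X_i beta))`; the generator has no intercept
#' term, so the event rate is governed entirely by the predictor mean and
#' the coefficient image.
#'
#' @param X Predictor matrix.
#' @param beta_true Coefficient vector, one entry per column of `X`.
#' @param seed Optional integer seed.
#' @return An integer 0/1 vector.
#' @export
simulate_outcomes <- function(X, beta_true, seed = NULL) {
  if (ncol(X) != length(beta_true)) {
    rlang::abort("`beta_true` must have one entry per column of `X`.")
  }
  p <- stats::plogis(drop(X %*% beta_true))
  draw <- function() stats::rbinom(nrow(X), 1L, p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate one complete simulated dataset
#'
#' Composes [build_beta_image()], [simulate_predictors()] and
#' [simulate_outcomes()]. The master seed is expanded into independent
#' sub-seeds for the predictor and outcome draws, so the whole dataset is
#' reproducible from `(scenario, seed)`.
#'
#' @param scenario A [sim_scenario].
#' @param seed Integer master seed.
#' @param path Optional file path; when given, the dataset (feature columns
#'   plus `y`) is written as CSV and the true coefficient image as
#'   `<path>_beta.csv`.
#' @return An object of class `sim_dataset`: a list with `data` (tibble of
#'   features plus `y`), `X`, `y`, `beta_true`, `scenario`, `seed`.
#' @export
#' @examples
#' d <- generate_dataset(sim_scenario(n_rows = 6, n_cols = 6, n_subjects = 40,
#'                                    signal_radius = 1), seed = 1)
#' dim(d$X)
generate_dataset <- function(scenario, seed, path = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  beta_true <- build_beta_image(scenario)
  X <- simulate_predictors(scenario, scenario$n_subjects, seed = sub[1L])
  y <- simulate_outcomes(X, beta_true, seed = sub[2L])
  data <- tibble::as_tibble(X)
  data$y <- y
  out <- structure(list(data = data, X = X, y = y, beta_true = beta_true,
                        scenario = scenario, seed = seed),
                   class = "sim_dataset")
  if (!is.null(path)) {
    readr::write_csv(data, path)
    readr::write_csv(tibble::tibble(term = colnames(X), beta = beta_true),
                     paste0(tools::file_path_sans_ext(path), "_beta.csv"))
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> N = ", nrow(x$X), ", J = ", ncol(x$X),
      ", event rate ", sprintf("%.1f%%", 100 * mean(x$y)),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
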