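test_that("unpenalized coordinate descent recovers the logistic MLE", {
  fx <- toy_logistic(n = 20, j = 2, seed = 42)
  fit <- cd_logistic(fx$X, fx$y, penalty_nu = 0, xi = 1)
  ml <- glm(fx$y ~ fx$X, family = binomial)
  expect_equal(c(fit$intercept, fit$beta), unname(coef(ml)),
               tolerance = 1e-6)
})

test_that("an overwhelming penalty returns the null model", {
  fx <- toy_logistic(n = 40, j = 3, seed = 2)
  fit <- cd_logistic(fx$X, fx$y, penalty_nu = 1e10, xi = 1)
  expect_equal(fit$beta, rep(0, 3))
  expect_equal(fit$intercept, qlogis(mean(fx$y)), tolerance = 1e-8)
})

test_that("one-dimensional lasso solution matches a grid-search oracle", {
  fx <- toy_logistic(n = 30, j = 1, n_signal = 1, seed = 7)
  nu <- 4
  fit <- cd_logistic(fx$X, fx$y, penalty_nu = nu, xi = 1)
  # profile the intercept out at each beta on a fine grid
  obj <- function(b) {
    prof <- optimize(function(b0) {
      eta <- b0 + fx$X[, 1] * b
      sum(fx$y * eta - log1p(exp(eta)))
    }, c(-5, 5), maximum = TRUE)
    prof$objective - nu * abs(b)
  }
  grid <- seq(-1.5, 1.5, by = 1e-4)
  best <- grid[which.max(vapply(grid, obj, numeric(1)))]
  expect_equal(fit$beta, best, tolerance = 2e-4)
})

test_that("fixed-penalty solutions match glmnet at matched scales", {
  # our objective: l(beta) - nu * (xi|b| + (1-xi)/2 b^2); glmnet minimizes
  # -(1/N) l + lambda (xi|b| + (1-xi)/2 b^2), so lambda = nu / N
  fx <- toy_logistic(n = 50, j = 8, n_signal = 3, seed = 10)
  std <- ssenet:::standardize_design(fx$X)
  for (xi in c(0.5, 1)) {
    s <- 0.2
    gn <- glmnet::glmnet(std$X, fx$y, family = "binomial", alpha = xi,
                         lambda = (1 / s) / 50, standardize = FALSE,
                         thresh = 1e-14)
    ours <- cd_logistic(std$X, fx$y, penalty_nu = 1 / s, xi = xi)
    expect_equal(ours$intercept, as.numeric(gn$a0), tolerance = 1e-6)
    expect_equal(ours$beta, as.numeric(gn$beta), tolerance = 1e-6)
  }
})

test_that("traditional fits equal the fixed-penalty solver through fit_ssen", {
  fx <- toy_logistic(seed = 42)
  std <- ssenet:::standardize_design(fx$X)
  for (xi in c(0.5, 1)) {
    model <- if (xi == 1) "lasso" else "en"
    fit <- fit_ssen(fx$data, "y", ss_prior(model, s0 = 0.15))
    ref <- cd_logistic(std$X, fx$y, penalty_nu = 1 / 0.15, xi = xi)
    expect_equal(fit$beta_std, ref$beta, tolerance = 1e-6)
  }
})

test_that("all-zero predictors give the base-rate intercept model", {
  d <- tibble::tibble(x1 = rep(0, 30), x2 = rep(0, 30),
                      y = rep(c(0L, 1L), c(20, 10)))
  fit <- fit_ssen(d, "y", ss_prior("ssen", s0 = 0.1, s1 = 1))
  expect_equal(unname(fit$beta), c(0, 0))
  expect_equal(fit$intercept, qlogis(1 / 3), tolerance = 1e-6)
  expect_equal(unique(predict(fit, d[1:5, 1:2])), 1 / 3, tolerance = 1e-6)
})

test_that("spike-and-slab fit with s0 = s1 collapses to the traditional fit", {
  fx <- toy_logistic(seed = 3)
  s <- 0.25
  ss <- fit_ssen(fx$data, "y", ss_prior(xi = 1, s0 = s, s1 = s))
  tr <- fit_ssen(fx$data, "y", ss_prior("lasso", s0 = s))
  expect_equal(ss$beta, tr$beta, tolerance = 1e-6)
  expect_equal(ss$p, ss$theta) # E-step collapses when components coincide
})

test_that("predictions follow the logit link", {
  fx <- toy_logistic(seed = 4)
  fit <- fit_ssen(fx$data, "y", ss_prior("ssl", s0 = 0.2, s1 = 1))
  # hand-built fit: known coefficients
  fake <- fit
  fake$intercept <- log(3)
  fake$beta[] <- 0
  preds <- fx$data[colnames(fx$X)]
  expect_equal(unique(predict(fake, preds[1:3, ])), 0.75)
  # probabilities are monotone in a positive-coefficient predictor
  fake$beta[1] <- 1
  grid <- fx$data[rep(1, 11), colnames(fx$X)]
  grid$x01 <- seq(-2, 2, length.out = 11)
  expect_true(all(diff(predict(fake, grid)) > 0))
  expect_error(predict(fit, fx$X[, 1:3]), "column")
})

test_that("fitting is deterministic and invariant to predictor rescaling", {
  fx <- toy_logistic(seed = 12)
  pr <- ss_prior("ssen", s0 = 0.2, s1 = 1)
  f1 <- fit_ssen(fx$data, "y", pr)
  f2 <- fit_ssen(fx$data, "y", pr)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$p, f2$p)
  # rescale one column; predictions on the rescaled data must not change
  d2 <- fx$data
  d2$x01 <- d2$x01 * 100
  f3 <- fit_ssen(d2, "y", pr)
  expect_equal(predict(f3, d2[colnames(fx$X)]),
               predict(f1, fx$data[colnames(fx$X)]), tolerance = 1e-8)
})

test_that("the penalized objective trace is non-decreasing on fixtures", {
  g <- lattice_adjacency(5, 5)
  fx <- toy_logistic(n = 90, j = 25, n_signal = 4, beta = 0.8, seed = 21)
  for (model in c("ssl", "ssen", "ssl_iar", "ssen_iar")) {
    pr <- ss_prior(model, s0 = 0.1, s1 = 1)
    fit <- suppressWarnings(
      fit_ssen(fx$data, "y", pr, graph = if (pr$spatial) g))
    expect_true(all(diff(fit$objective_trace) > -1e-8),
                info = model)
  }
})

test_that("signal locations get larger inclusion probabilities than nulls", {
  sc <- mini_scenario()
  g <- lattice_adjacency(sc$n_rows, sc$n_cols)
  hits <- 0L
  for (s in 1:10) {
    d <- generate_dataset(sc, seed = s)
    fit <- suppressWarnings(
      ssenet:::fit_ssen_impl(d$X, d$y, ss_prior("ssen_iar", s0 = 0.2, s1 = 2), g))
    hits <- hits +
      (mean(fit$p[d$beta_true != 0]) > mean(fit$p[d$beta_true == 0]))
  }
  expect_gte(hits, 9L)
})

test_that("the IAR fit's prior field is smoother than the non-spatial
           fit's implied inclusion logits", {
  sc <- mini_scenario()
  g <- lattice_adjacency(sc$n_rows, sc$n_cols)
  for (s in 1:10) {
    d <- generate_dataset(sc, seed = 100 + s)
    ns <- suppressWarnings(
      ssenet:::fit_ssen_impl(d$X, d$y, ss_prior("ssen", s0 = 0.2, s1 = 2), NULL))
    sp <- suppressWarnings(
      ssenet:::fit_ssen_impl(d$X, d$y, ss_prior("ssen_iar", s0 = 0.2, s1 = 2), g))
    expect_lte(lap_quad(g, sp$psi), lap_quad(g, clip_logit(ns$p)) + 1e-8)
  }
})

test_that("fit errors are informative", {
  fx <- toy_logistic(seed = 5)
  d_one <- fx$data
  d_one$y <- 0L
  expect_error(fit_ssen(d_one, "y", ss_prior("ssl", s0 = 0.1, s1 = 1)),
               "Both outcome classes")
  expect_error(
    fit_ssen(fx$data, "y", ss_prior("ssen_iar", s0 = 0.1, s1 = 1),
             graph = lattice_adjacency(2, 2)),
    "one node per predictor")
  expect_error(fit_ssen(fx$data, "y", ss_prior("ssl_iar", s0 = 0.1, s1 = 1)),
               "graph is required")
  d_na <- fx$data
  d_na$x01[3] <- NA
  expect_error(fit_ssen(d_na, "y", ss_prior("ssl", s0 = 0.1, s1 = 1)),
               "Missing")
})

test_that("tidy and glance expose the fit in rectangular form", {
  fx <- toy_logistic(seed = 6)
  fit <- fit_ssen(fx$data, "y", ss_prior("ssen", s0 = 0.2, s1 = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  expect_named(td, c("term", "estimate", "inclusion_prob", "prior_prob"))
  gl <- glance(fit)
  expect_equal(gl$n_predictors, 5)
  expect_true(gl$converged)
})
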