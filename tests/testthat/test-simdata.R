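test_that("the default coefficient image is a 49-point disc", {
  sc <- sim_scenario()
  b <- build_beta_image(sc)
  expect_length(b, 1600)
  expect_equal(sum(b != 0), 49)
  expect_equal(sum(b), 49 * 0.10)
  # enumerate (dx, dy) with dx^2 + dy^2 <= 16 as an independent count
  offs <- expand.grid(dx = -4:4, dy = -4:4)
  expect_equal(sum(offs$dx^2 + offs$dy^2 <= 16), 49)
  b05 <- build_beta_image(sim_scenario(signal_value = 0.05))
  expect_equal(sum(b05), 2.45)
})

test_that("radius zero marks only the centre and the disc must fit", {
  sc <- sim_scenario(signal_radius = 0)
  b <- build_beta_image(sc)
  expect_equal(sum(b != 0), 1)
  idx <- which(b != 0)
  expect_equal(idx, (20 - 1) * 40 + 20) # row-major centre
  expect_error(sim_scenario(n_rows = 6, n_cols = 6, signal_center = c(2, 3),
                            signal_radius = 4),
               "fit inside")
})

test_that("row-major vectorization round-trips through the image", {
  sc <- sim_scenario(n_rows = 5, n_cols = 7, n_subjects = 10,
                     signal_center = c(3, 4), signal_radius = 1)
  b <- build_beta_image(sc)
  img <- matrix(b, nrow = 5, ncol = 7, byrow = TRUE)
  expect_equal(as.vector(t(img)), b)
  expect_equal(img[3, 4], sc$signal_value)       # centre
  expect_equal(img[3, c(3, 5)], rep(sc$signal_value, 2)) # radius-1 arms
  expect_equal(img[1, 1], 0)
})

test_that("predictors reproduce the stated mean and correlation decay", {
  sc <- sim_scenario(n_rows = 6, n_cols = 6, n_subjects = 5000,
                     signal_center = c(3, 3), signal_radius = 1)
  X <- simulate_predictors(sc, n = 5000, seed = 44)
  expect_equal(dim(X), c(5000L, 36L))
  expect_lt(max(abs(colMeans(X) - (-1))), 0.05)
  C <- cor(X)
  # adjacent pair, distance 2, and a distance-5 pair along a row
  expect_equal(C[1, 2], 0.9, tolerance = 0.02)
  expect_equal(C[1, 3], 0.81, tolerance = 0.02)
  expect_equal(C[1, 6], 0.9^5, tolerance = 0.02)
  # distance sqrt(2) diagonal neighbour
  expect_equal(C[1, 8], 0.9^sqrt(2), tolerance = 0.02)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 0.05)
})

test_that("outcomes follow the logit law of the generator", {
  sc <- mini_scenario()
  X <- simulate_predictors(sc, n = 4000, seed = 3)
  # beta = 0 gives a fair coin regardless of X
  y0 <- simulate_outcomes(X, rep(0, ncol(X)), seed = 4)
  expect_equal(mean(y0), 0.5, tolerance = 0.03)
  # rate matches plogis(X beta) on average for the scenario's own beta
  b <- build_beta_image(sc)
  y <- simulate_outcomes(X, b, seed = 5)
  expect_equal(mean(y), mean(plogis(X %*% b)), tolerance = 0.03)
  expect_true(all(y %in% c(0L, 1L)))
  expect_error(simulate_outcomes(X, c(1, 2)), "one entry per column")
})

test_that("datasets are reproducible and have the documented shape", {
  sc <- sim_scenario()
  d1 <- generate_dataset(sc, seed = 8)
  d2 <- generate_dataset(sc, seed = 8)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  expect_equal(dim(d1$X), c(250L, 1600L))
  expect_named(d1$data, c(sprintf("x%04d", 1:1600), "y"))
  d3 <- generate_dataset(sc, seed = 9)
  expect_false(identical(d1$y, d3$y))
})

test_that("dataset CSVs round-trip through readr", {
  sc <- mini_scenario(n_subjects = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- generate_dataset(sc, seed = 2, path = path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(d$data))
  bmap <- readr::read_csv(sub("\\.csv$", "_beta.csv", path),
                          show_col_types = FALSE)
  expect_equal(bmap$beta, d$beta_true)
})

test_that("the true model's held-out performance bounds what any
           classifier can achieve under each condition", {
  # plogis(X beta_true) is the exact conditional event probability, so in
  # expectation no fitted classifier beats it on deviance, AUC, MSE, or —
  # jointly with specificity — the threshold metrics. These reference
  # values calibrate how cross-validated fits should be read.
  truth_metrics <- function(sc, seeds) {
    rows <- lapply(seeds, function(s) {
      d <- generate_dataset(sc, seed = 7000 + s)
      ssenet:::all_metrics(d$y, plogis(drop(d$X %*% d$beta_true)))
    })
    dplyr::summarise(dplyr::bind_rows(rows),
                     dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)))
  }
  large <- truth_metrics(sim_scenario(), 1:60)
  expect_equal(large$auc, 0.962, tolerance = 0.02 / 0.962)
  expect_equal(large$deviance, 81.0, tolerance = 8 / 81)
  expect_equal(large$mse, 0.049, tolerance = 0.008 / 0.049)
  expect_equal(large$sn, 0.685, tolerance = 0.06 / 0.685)
  expect_equal(large$mcc, 0.703, tolerance = 0.06 / 0.703)
  small <- truth_metrics(
    sim_scenario(signal_value = 0.05, predictor_mean = -1.25), 1:60)
  expect_equal(small$auc, 0.882, tolerance = 0.03 / 0.882)
  expect_equal(small$sn, 0.367, tolerance = 0.08 / 0.367)
  expect_equal(small$mcc, 0.446, tolerance = 0.08 / 0.446)
  expect_equal(small$f1, 0.470, tolerance = 0.08 / 0.470)
})
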