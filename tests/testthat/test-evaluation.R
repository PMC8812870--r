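test_that("binomial deviance matches closed-form values", {
  expect_equal(binomial_deviance(c(0, 1, 0, 1), rep(0.5, 4)), 8 * log(2))
  expect_equal(binomial_deviance(c(1, 0), c(0.8, 0.3)),
               -2 * (log(0.8) + log(0.7)))
  expect_lt(binomial_deviance(c(0, 1, 1), c(0, 1, 1)), 1e-8)
  expect_error(binomial_deviance(c(0, 1), 0.5), "equal length")
})

test_that("prediction-error metrics follow their printed definitions", {
  # p = 0.5 everywhere: MC uses a strict inequality, so nothing is
  # misclassified even though every |y - p| equals 0.5
  m <- prediction_error_metrics(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(m$mse, 0.25)
  expect_equal(m$mae, 0.5)
  expect_equal(m$mc, 0)
  m2 <- prediction_error_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(m2$auc, 0.75) # 3 of 4 positive-negative pairs concordant
  m3 <- prediction_error_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(c(m3$mse, m3$mae, m3$mc), c(0, 0, 0))
  expect_equal(m3$auc, 1)
  expect_true(is.na(prediction_error_metrics(c(1, 1), c(0.2, 0.4))$auc))
})

test_that("AUC equals brute-force pair counting with half ties", {
  withr::with_seed(13, {
    for (i in 1:200) {
      n <- sample(5:40, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      p <- round(runif(n), sample(c(1, 2), 1)) # coarse grid forces ties
      pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
      brute <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                           ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
      expect_equal(prediction_error_metrics(y, p)$auc, brute)
    }
  })
})

test_that("classification thresholds strictly", {
  expect_equal(classify(c(0.49, 0.5, 0.51)), c(0L, 0L, 1L))
  expect_equal(classify(rep(0.7, 3)), rep(1L, 3))
  expect_error(classify(0.5, threshold = 0), "strictly inside")
  expect_error(classify(0.5, threshold = 1), "strictly inside")
})

test_that("confusion metrics match direct evaluation", {
  perfect <- confusion_metrics(confusion_counts(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_true(all(perfect == 1))
  chance <- confusion_metrics(confusion_counts(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(chance$mcc, 0)
  expect_equal(chance$f1, 0.5)
  expect_equal(chance$ac, 0.5)
  m <- confusion_metrics(confusion_counts(tp = 30, fp = 4, tn = 230, fn = 9))
  expect_equal(m$sn, 30 / 39)
  expect_equal(m$sp, 230 / 234)
  expect_equal(m$ppv, 30 / 34)
  expect_equal(m$npv, 230 / 239)
  expect_equal(m$mcc, (30 * 230 - 4 * 9) / sqrt(34 * 39 * 234 * 239))
  expect_equal(m$f1, 60 / 73)
  expect_error(confusion_counts(tp = -1, fp = 0, tn = 0, fn = 1),
               "non-negative")
  # zero denominators propagate as missing
  m0 <- confusion_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m0$sn) && is.na(m0$ppv) && is.na(m0$mcc) && is.na(m0$f1))
})

test_that("MCC and F1 match brute-force formulas on random tables and MCC
           has its swap/inversion symmetries", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      k <- as.list(rpois(4, 6))
      names(k) <- c("tp", "fp", "tn", "fn")
      cc <- do.call(confusion_counts, k)
      m <- confusion_metrics(cc)
      den <- sqrt(prod(c(k$tp + k$fp, k$tp + k$fn,
                         k$tn + k$fp, k$tn + k$fn)))
      if (den > 0) {
        expect_equal(m$mcc, (k$tp * k$tn - k$fp * k$fn) / den)
        # swapping the class labels leaves MCC unchanged
        sw <- confusion_metrics(confusion_counts(tp = k$tn, fp = k$fn,
                                                 tn = k$tp, fn = k$fp))
        expect_equal(sw$mcc, m$mcc)
        # inverting predictions flips its sign
        inv <- confusion_metrics(confusion_counts(tp = k$fn, fp = k$tn,
                                                  tn = k$fp, fn = k$tp))
        expect_equal(inv$mcc, -m$mcc)
      }
      if (2 * k$tp + k$fp + k$fn > 0) {
        expect_equal(m$f1, 2 * k$tp / (2 * k$tp + k$fp + k$fn))
      }
    }
  })
})

test_that("stratified folds cover every subject once per repeat", {
  y <- rep(c(0, 1), c(8, 2))
  folds <- ssenet:::make_folds(y, k = 2, seed = 1, repeats = 3)
  expect_equal(dim(folds), c(10L, 3L))
  for (r in 1:3) {
    expect_setequal(folds[, r], 1:2)
    # each fold holds exactly one event
    expect_equal(as.integer(table(folds[y == 1, r])), c(1L, 1L))
  }
  folds5 <- ssenet:::make_folds(rep(c(0, 1), 5), k = 5, seed = 2)
  expect_equal(as.integer(table(folds5)), rep(2L, 5))
  expect_error(ssenet:::make_folds(y, k = 3, seed = 1), "smaller k")
})

test_that("cross-validation yields one held-out prediction per subject and
           base-rate predictions for constant predictors", {
  d <- tibble::tibble(x1 = rep(1, 10), y = rep(c(0L, 1L), c(6, 4)))
  cv <- kfold_cv(d, "y", ss_prior("ssl", s0 = 0.2, s1 = 1), k = 2, seed = 5)
  expect_setequal(cv$predictions$row, 1:10)
  # with a constant predictor each held-out prediction is the training fold
  # base rate, so CV deviance is the null-model deviance of those rates
  folds <- ssenet:::make_folds(d$y, 2, seed = 5)
  for (f in 1:2) {
    rate <- mean(d$y[folds[, 1] != f])
    expect_equal(cv$predictions$p_hat[cv$predictions$fold == f],
                 rep(rate, 5), tolerance = 1e-6)
  }
  expect_equal(cv$summary$deviance,
               binomial_deviance(cv$predictions$y, cv$predictions$p_hat))
})

test_that("pooled-prediction metrics agree with pooled confusion counts", {
  fx <- toy_logistic(n = 80, j = 4, seed = 31)
  cv <- kfold_cv(fx$data, "y", ss_prior("ssen", s0 = 0.2, s1 = 1),
                 k = 4, seed = 9)
  cm <- confusion_metrics(
    confusion_counts(cv$predictions$y, classify(cv$predictions$p_hat)))
  expect_equal(cv$summary$ac, cm$ac)
  expect_equal(cv$summary$sn, cm$sn)
  expect_equal(cv$summary$mcc, cm$mcc)
  # repeated CV is reproducible bit for bit
  cv2 <- kfold_cv(fx$data, "y", ss_prior("ssen", s0 = 0.2, s1 = 1),
                  k = 4, seed = 9)
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("grid selection minimizes CV deviance with documented tie-breaks", {
  fx <- toy_logistic(n = 60, j = 4, seed = 17)
  expect_message(
    gs <- grid_select(fx$data, "y", ss_prior("ssen", s0 = 0.1, s1 = 1),
                      s0_grid = c(0.1, 0.3, 1.5), s1_grid = c(1, 2),
                      k = 3, seed = 2),
    "Skipped 1")
  expect_equal(nrow(gs$grid), 5L) # (1.5, 1) dropped
  # chosen point attains the minimum of an exhaustive re-scan
  expect_equal(gs$best$deviance, min(gs$grid$deviance))
  rescan <- dplyr::arrange(gs$grid, deviance, s0, s1)[1, ]
  expect_equal(gs$best$s0, rescan$s0)
  expect_equal(gs$best$s1, rescan$s1)
  expect_error(
    grid_select(fx$data, "y", ss_prior("ssen", s0 = 0.1, s1 = 1),
                s0_grid = 2, s1_grid = 1, k = 3, seed = 2),
    "No admissible")
})
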