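# Small fixtures shared across test files; everything is generated in code.

# logistic toy data with a few informative predictors
toy_logistic <- function(n = 60, j = 5, n_signal = 2, beta = 1, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * j), n, j,
                dimnames = list(NULL, sprintf("x%02d", seq_len(j))))
    b <- c(rep(beta, n_signal), rep(0, j - n_signal))
    y <- rbinom(n, 1, plogis(X %*% b))
    list(X = X, y = y, beta = b,
         data = {
           d <- tibble::as_tibble(X)
           d$y <- y
           d
         })
  })
}

# small lattice scenario with a strong signal disc, kept fast to simulate
mini_scenario <- function(signal_value = 1, predictor_mean = 0,
                          n_subjects = 150) {
  sim_scenario(n_rows = 6, n_cols = 6, n_subjects = n_subjects,
               signal_value = signal_value, predictor_mean = predictor_mean,
               signal_center = c(3, 3), signal_radius = 1.5)
}

# Laplacian quadratic form
lap_quad <- function(graph, v) {
  L <- graph_laplacian(graph)
  as.numeric(Matrix::crossprod(v, L %*% v))
}

clip_logit <- function(p, bound = 8) {
  qlogis(pmin(pmax(p, plogis(-bound)), plogis(bound)))
}
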