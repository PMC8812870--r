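#' Spike-and-slab elastic net prior specification
#'
#' Defines which of the six supported model variants is fit. A prior is a
#' two-component scale mixture on each coefficient: a narrow "spike"
#' (scale `s0`, strong shrinkage, for irrelevant predictors) and a wide
#' "slab" (scale `s1`, weak shrinkage, for relevant predictors), selected by
#' a latent Bernoulli inclusion indicator. The mixture weight `xi` blends
#' lasso-type (`xi = 1`) and ridge-type (`xi = 0`) components; `xi = 0.5`
#' gives the elastic net variants. Turning `spike_slab` off collapses both
#' scales to a single penalty scale (`s0 = s1 = lambda`), the traditional
#' lasso/elastic net. Turning `spatial` on replaces the global update of
#' the prior inclusion probabilities with an intrinsic autoregressive (IAR)
#' smoothing over a supplied neighbour graph.
#'
#' @param model Optional shorthand: one of `"lasso"`, `"en"`, `"ssl"`,
#'   `"ssen"`, `"ssl_iar"`, `"ssen_iar"` (hyphens also accepted). Sets
#'   `xi`, `spike_slab` and `spatial`; `s0`/`s1` must still be supplied.
#' @param s0 Spike scale (> 0). For traditional models this is the single
#'   penalty scale.
#' @param s1 Slab scale (>= s0). Defaults to `s0` for traditional models.
#' @param xi Mixture weight in `[0, 1]`; ignored when `model` is given.
#' @param spike_slab Logical; `FALSE` fits the traditional single-scale
#'   penalty (requires `s0 == s1`).
#' @param spatial Logical; `TRUE` requests the IAR update of the prior
#'   inclusion probabilities (requires a graph at fit time).
#' @param tau IAR precision scale (default 1, the usual convention).
#' @param density_form `"printed"` (default) or `"normalized"`: which form
#'   of the mixture component densities the E-step uses (see
#'   [en_log_density()]).
#' @return An object of class `ss_prior`.
#' @export
#' @examples
#' ss_prior("ssen_iar", s0 = 0.1, s1 = 2)
#' ss_prior(xi = 1, s0 = 0.05, s1 = 1, spike_slab = TRUE, spatial = FALSE)
ss_prior <- function(model = NULL, s0, s1 = NULL, xi = 0.5,
                     spike_slab = TRUE, spatial = FALSE, tau = 1,
                     density_form = c("printed", "normalized")) {
  density_form <- match.arg(density_form)
  if (!is.null(model)) {
    model <- gsub("-", "_", tolower(model))
    settings <- list(
      lasso    = list(xi = 1,   spike_slab = FALSE, spatial = FALSE),
      en       = list(xi = 0.5, spike_slab = FALSE, spatial = FALSE),
      ssl      = list(xi = 1,   spike_slab = TRUE,  spatial = FALSE),
      ssen     = list(xi = 0.5, spike_slab = TRUE,  spatial = FALSE),
      ssl_iar  = list(xi = 1,   spike_slab = TRUE,  spatial = TRUE),
      ssen_iar = list(xi = 0.5, spike_slab = TRUE,  spatial = TRUE)
    )
    if (!model %in% names(settings)) {
      rlang::abort(paste0("Unknown model '", model, "'. Choose one of: ",
                          paste(names(settings), collapse = ", "), "."))
    }
    s <- settings[[model]]
    xi <- s$xi; spike_slab <- s$spike_slab; spatial <- s$spatial
  }
  if (missing(s0)) rlang::abort("`s0` must be supplied.")
  if (is.null(s1)) {
    if (spike_slab) rlang::abort("`s1` must be supplied for spike-and-slab priors.")
    s1 <- s0
  }
  if (!is.numeric(xi) || length(xi) != 1L || is.na(xi) || xi < 0 || xi > 1) {
    rlang::abort("`xi` must be a single number in [0, 1].")
  }
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 <= 0) {
    rlang::abort("`s0` must be a single positive number.")
  }
  if (!is.numeric(s1) || length(s1) != 1L || is.na(s1) || s1 < s0) {
    rlang::abort("`s1` must be a single number with s1 >= s0.")
  }
  if (!spike_slab && s0 != s1) {
    rlang::abort("Traditional (non spike-and-slab) priors require s0 == s1.")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    rlang::abort("`tau` must be a single positive number.")
  }
  structure(list(model = model, xi = xi, s0 = s0, s1 = s1,
                 spike_slab = isTRUE(spike_slab), spatial = isTRUE(spatial),
                 tau = tau, density_form = density_form),
            class = "ss_prior")
}

#' @export
print.ss_prior <- function(x, ...) {
  kind <- if (x$spike_slab) "spike-and-slab" else "traditional"
  cat("<ss_prior> ", kind,
      if (x$spatial) " + IAR" else "",
      "  xi = ", x$xi, ", s0 = ", x$s0, ", s1 = ", x$s1,
      if (x$spatial) paste0(", tau = ", x$tau) else "",
      "\n", sep = "")
  invisible(x)
}

#' Log density of the elastic net mixture component
#'
#' Evaluates the log of the elastic net scale-mixture density
#' \deqn{EN(\beta \mid 0, S) = (1-\xi)\exp(-\log(2\pi S) - \beta^2/S) +
#'   \xi \exp(-\log(2S) - |\beta|/S)}
#' via log-sum-exp. This is the `"printed"` form; the `"normalized"` form
#' instead uses the properly normalised Gaussian
#' \eqn{N(0, S)} component \eqn{\exp(-\tfrac12\log(2\pi S) - \beta^2/(2S))}
#' (the double-exponential component is already normalised). Only ratios of
#' the same form enter the E-step, so either choice is internally
#' consistent; `"printed"` is the default.
#'
#' @param beta Numeric vector of coefficient values.
#' @param scale Positive scale `S` (scalar or vector recycled with `beta`).
#' @param xi Mixture weight in `[0, 1]`.
#' @param form `"printed"` or `"normalized"`.
#' @return Numeric vector of log densities.
#' @export
#' @examples
#' en_log_density(0, 1, 1)  # log(1/2)
#' en_log_density(0, 1, 0)  # log(1/(2*pi))
en_log_density <- function(beta, scale, xi,
                           form = c("printed", "normalized")) {
  form <- match.arg(form)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    rlang::abort("`scale` must be positive.")
  }
  if (any(xi < 0 | xi > 1)) rlang::abort("`xi` must lie in [0, 1].")
  if (form == "printed") {
    a_gauss <- -log(2 * pi * scale) - beta^2 / scale
  } else {
    a_gauss <- -0.5 * log(2 * pi * scale) - beta^2 / (2 * scale)
  }
  a_de <- -log(2 * scale) - abs(beta) / scale
  if (length(xi) == 1L) {
    if (xi == 0) return(a_gauss + 0)
    if (xi == 1) return(a_de + 0)
  }
  la <- log1p(-xi) + a_gauss
  lb <- log(xi) + a_de
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m))
}

#' E-step posterior inclusion probabilities
#'
#' Conditional probability that a coefficient belongs to the slab component
#' given its current value and prior inclusion probability:
#' \deqn{p_j = \frac{\theta_j EN(\beta_j \mid 0, s_1)}
#'   {\theta_j EN(\beta_j \mid 0, s_1) + (1-\theta_j) EN(\beta_j \mid 0, s_0)}}
#' computed in log space.
#'
#' @param beta Numeric vector of coefficient values (standardized scale).
#' @param theta Prior inclusion probabilities in `(0, 1)` (scalar or vector).
#' @param prior An [ss_prior] with `spike_slab = TRUE`.
#' @return Numeric vector of posterior inclusion probabilities.
#' @export
e_step_inclusion <- function(beta, theta, prior) {
  stopifnot(inherits(prior, "ss_prior"))
  if (!prior$spike_slab) {
    rlang::abort("E-step requires a spike-and-slab prior.")
  }
  if (any(theta <= 0 | theta >= 1)) {
    rlang::abort("`theta` must lie strictly within (0, 1).")
  }
  l1 <- en_log_density(beta, prior$s1, prior$xi, prior$density_form)
  l0 <- en_log_density(beta, prior$s0, prior$xi, prior$density_form)
  # p = 1 / (1 + exp(log odds against inclusion))
  stats::plogis(stats::qlogis(theta) + l1 - l0)
}

#' Effective inverse penalty scale
#'
#' Expected inverse mixture scale \eqn{\nu_j = p_j/s_1 + (1-p_j)/s_0}, used
#' as the per-coefficient penalty multiplier in the M-step: larger posterior
#' inclusion probability means the coefficient is penalised at the weaker
#' slab rate.
#'
#' @param p Posterior inclusion probabilities in `[0, 1]`.
#' @param prior An [ss_prior].
#' @return Numeric vector of effective inverse scales, elementwise within
#'   `[1/s1, 1/s0]`.
#' @export
effective_inverse_scale <- function(p, prior) {
  stopifnot(inherits(prior, "ss_prior"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("`p` must lie in [0, 1].")
  }
  p / prior$s1 + (1 - p) / prior$s0
}
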