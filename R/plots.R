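# lattice helper: turn a per-location vector into a plotting tibble
lattice_tbl <- function(values, n_rows, n_cols, name = "value") {
  xy <- lattice_coords(n_rows, n_cols)
  tibble::tibble(row = xy[, 1L], col = xy[, 2L], !!name := values)
}

#' Plot a fitted classifier
#'
#' For fits whose graph is a lattice (from [lattice_adjacency()]), draws
#' the requested per-location field as an image; otherwise draws the
#' non-zero coefficients as a segment plot.
#'
#' @param object An `ssen_fit`.
#' @param what `"inclusion"` (posterior inclusion probabilities, default
#'   when available) or `"coef"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssen_fit <- function(object, what = c("inclusion", "coef"), ...) {
  what <- match.arg(what)
  if (what == "inclusion" && is.null(object$p)) what <- "coef"
  values <- if (what == "inclusion") object$p else unname(object$beta)
  lab <- if (what == "inclusion") "Pr(include)" else "coefficient"
  dims <- if (!is.null(object$graph)) attr(object$graph, "lattice_dim")
  if (!is.null(dims)) {
    df <- lattice_tbl(values, dims[1L], dims[2L])
    ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(fill = lab, x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(term = object$feature_names, value = values)
    df <- df[df$value != 0 | what == "inclusion", ]
    ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$value)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$term, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = NULL, y = lab) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         vjust = 0.5))
  }
}

#' Plot the true coefficient image of a simulated dataset
#'
#' @param object A `sim_dataset` from [generate_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_dataset <- function(object, ...) {
  sc <- object$scenario
  df <- lattice_tbl(object$beta_true, sc$n_rows, sc$n_cols, "beta")
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$beta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "true beta", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated deviance over the scale grid
#'
#' @param object An `ssen_grid` from [grid_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssen_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(factor(.data$s0), factor(.data$s1),
                               fill = .data$deviance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 4, size = 3) +
    ggplot2::labs(x = "spike scale s0", y = "slab scale s1",
                  fill = "CV deviance") +
    ggplot2::theme_minimal()
}

#' Plot per-model classification performance of a study
#'
#' One panel per metric, one point per model (the mean over replicate
#' datasets), in the spirit of the usual classification-performance dot
#' plots for multi-model comparisons.
#'
#' @param object An `ssen_study` from [run_study()].
#' @param metrics Character vector of aggregate metric columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssen_study <- function(object,
                                metrics = c("ac", "sn", "sp", "ppv",
                                            "npv", "mcc", "f1"), ...) {
  df <- object$aggregate |>
    dplyr::select("model", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"model", names_to = "metric")
  df$model <- factor(df$model, levels = model_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean over replicate datasets") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
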