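## ggplot2 views of the main result types.

#' Plot band dispersion components against elevation
#'
#' One panel per component (alpha, beta-within, gamma), points per
#' band, faceted by dispersion facet when present.
#'
#' @param band_tbl Output of [dispersion_by_band()] (optionally with a
#'   `facet` column, as in a pipeline run).
#' @return A ggplot object.
#' @export
plot_band_components <- function(band_tbl) {
  long <- tidyr::pivot_longer(band_tbl,
                              cols = dplyr::any_of(c("alpha",
                                                     "beta_within",
                                                     "gamma")),
                              names_to = "component",
                              values_to = "dispersion")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$band,
                                          y = .data$dispersion)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "Elevational band (m)",
                  y = "Dispersion (S.E.S.)") +
    ggplot2::theme_minimal()
  if ("facet" %in% names(long)) {
    p + ggplot2::facet_grid(facet ~ component)
  } else {
    p + ggplot2::facet_wrap(~component)
  }
}

#' Distance-decay plot of band-pair beta dispersion
#'
#' S.E.S. D_pw between pooled band pairs against their elevational
#' difference.
#'
#' @param beta_tbl Output of [band_beta_matrix()] (optionally with a
#'   `facet` column).
#' @return A ggplot object.
#' @export
plot_distance_decay <- function(beta_tbl) {
  df <- dplyr::mutate(beta_tbl,
                      dist_ele = abs(.data$band2 - .data$band1))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dist_ele,
                                        y = .data$ses)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "Elevational difference (m)",
                  y = "S.E.S. D_pw") +
    ggplot2::theme_minimal()
  if ("facet" %in% names(df)) p + ggplot2::facet_wrap(~facet) else p
}

#' @describeIn variation_partition Bar chart of unique and shared
#'   fractions (black: unique; grey: combined).
#' @param object A `variation_partition`.
#' @param ... Unused.
#' @method autoplot variation_partition
#' @export
autoplot.variation_partition <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "residual")
  df$kind <- ifelse(df$term == "combined", "combined", "unique")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term,
                                   y = .data$fraction,
                                   fill = .data$kind)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(unique = "black",
                                          combined = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(R^2 ~ "fraction")) +
    ggplot2::theme_minimal()
}

#' @describeIn ols_poly Scatter plot with the fitted curve.
#' @param object A `gradient_fit`.
#' @param ... Unused.
#' @method autoplot gradient_fit
#' @export
autoplot.gradient_fit <- function(object, ...) {
  df <- object$model$model
  names(df)[1:2] <- c("y", "x")
  grid <- data.frame(.x = seq(min(df$x), max(df$x), length.out = 100))
  grid$y <- stats::predict(object$model, newdata = grid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$.x, y = .data$y)) +
    ggplot2::labs(x = object$terms[1], y = object$response) +
    ggplot2::theme_minimal()
}
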