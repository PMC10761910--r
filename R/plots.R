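# ggplot2 methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed-versus-predicted diagnostic plot
#'
#' Scatter of observed against model-predicted droplet diameters (or rates)
#' with the 1:1 identity line.
#'
#' @param model A diameter model accepted by [predict_norm_diameter()].
#' @param data A droplet dataset with observed outcomes.
#' @param what `"diameter"` or `"rate"`.
#' @return A ggplot.
#' @export
plot_predictions <- function(model, data, what = c("diameter", "rate")) {
  what <- match.arg(what)
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  df <- if (what == "diameter") {
    tibble::tibble(observed = d$diameter_um,
                   predicted = predict_diameter(model, data))
  } else {
    tibble::tibble(observed = d$rate_hz,
                   predicted = predict_rate(model, data))
  }
  lab <- if (what == "diameter") "diameter (µm)" else "generation rate (Hz)"
  ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "red") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = paste("observed", lab), y = paste("predicted", lab)) +
    ggplot2::theme_minimal()
}

#' @describeIn parameter_importance Bar chart of mean gain shares with
#'   two-standard-deviation error bars.
#' @param object An `importance_report`.
#' @param ... Unused.
#' @export
autoplot.importance_report <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = stats::reorder(.data$feature, .data$mean_gain))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$mean_gain)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_gain - .data$dispersion / 2, 0),
      ymax = .data$mean_gain + .data$dispersion / 2), width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean gain share") +
    ggplot2::theme_minimal()
}

#' @describeIn stability_map Tile map of the signed GRD over the middle and
#'   outer flow axes (faceted by inner flow when it varies), with unstable
#'   regions classified by their mode of instability.
#' @param object A `de_stability_map`.
#' @param ... Unused.
#' @export
autoplot.de_stability_map <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$q_middle_ulh,
                                            .data$q_outer_ulh)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$grd_pct)) +
    ggplot2::geom_point(data = dplyr::filter(object,
                          .data$label != "stable_single_core"),
                        ggplot2::aes(shape = .data$label), size = 1) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "GRD (%)") +
    ggplot2::labs(x = "middle flow (µL/h)", y = "outer flow (µL/h)") +
    ggplot2::theme_minimal()
  if (length(unique(object$q_inner_ulh)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$q_inner_ulh))
  }
  p
}

#' @describeIn performance_heatmap Tile map of predicted diameter or rate
#'   over the swept flow rates.
#' @param object A `performance_heatmap`.
#' @param value Which prediction to map: `"diameter"` or `"rate"`.
#' @param ... Unused.
#' @export
autoplot.performance_heatmap <- function(object,
                                         value = c("diameter", "rate"), ...) {
  value <- match.arg(value)
  fill <- if (value == "diameter") "diameter_um" else "rate_hz"
  lab <- if (value == "diameter") "diameter (µm)" else "rate (Hz)"
  ggplot2::ggplot(object, ggplot2::aes(.data$q_c_ulh, .data$q_d_ulh)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$is_center),
                        shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "continuous flow (µL/h)",
                  y = "dispersed flow (µL/h)") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_diameter_nn Training and validation loss history.
#' @param object A `diameter_nn`.
#' @param ... Unused.
#' @export
autoplot.diameter_nn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean squared error") +
    ggplot2::theme_minimal()
}
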