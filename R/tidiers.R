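# broom-style tidy()/glance() methods for fitted objects and design results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_scaling_law Coefficients as a tibble (`term`, `estimate`).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.scaling_law <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @describeIn fit_scaling_law One-row model summary.
#' @export
glance.scaling_law <- function(x, ...) {
  tibble::tibble(form_id = x$form_id, n = x$n,
                 training_mape = x$training_mape,
                 r_squared = summary(x$fit)$r.squared)
}

#' @describeIn fit_diameter_nn One-row training summary.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance.diameter_nn <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_features = length(x$features),
    hidden = paste(x$spec$hidden, collapse = "x"),
    epochs_run = nrow(x$history), best_epoch = x$best_epoch,
    val_mse = x$val_loss, seed = x$spec$seed
  )
}

#' @describeIn fit_diameter_trees One-row training summary.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance.diameter_trees <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_features = length(x$features), n_trees = x$spec$n_trees,
    max_depth = x$spec$max_depth, learning_rate = x$spec$learning_rate,
    l2 = x$spec$l2, seed = x$spec$seed
  )
}

#' @describeIn fit_diameter_trees Per-feature gain shares of a single fitted
#'   ensemble.
#' @export
tidy.diameter_trees <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  share <- stats::setNames(rep(0, length(x$features)), x$features)
  share[imp$Feature] <- imp$Gain
  tibble::tibble(feature = names(share), gain = unname(share / sum(share)))
}

#' @describeIn design_se The solution as a one-row tibble.
#' @param x A `design_solution`.
#' @param ... Unused.
#' @export
tidy.design_solution <- function(x, ...) {
  g <- x$geometry
  tibble::tibble(
    orifice_width_um = g$orifice_width_um,
    channel_depth_um = g$channel_depth_um,
    dispersed_inlet_width_um = g$dispersed_inlet_width_um,
    continuous_inlet_width_um = g$continuous_inlet_width_um,
    outlet_width_um = g$outlet_width_um,
    continuous_flow_ulh = x$continuous_flow_ulh,
    dispersed_flow_ulh = x$dispersed_flow_ulh,
    capillary_number = x$capillary_number,
    flow_rate_ratio = x$flow_rate_ratio,
    predicted_diameter_um = x$predicted_diameter_um,
    predicted_rate_hz = x$predicted_rate_hz,
    cost = x$cost,
    converged = x$converged,
    iterations = x$iterations,
    provenance = x$provenance
  )
}

#' @describeIn design_de One-row search summary.
#' @param x A `de_design`.
#' @param ... Unused.
#' @export
glance.de_design <- function(x, ...) {
  tibble::tibble(
    found = x$found,
    n_stable = nrow(x$solutions),
    n_evaluated = x$n_evaluated,
    grd_threshold = x$grd_threshold,
    best_error_pct = if (x$found) x$best$error_pct else NA_real_,
    best_grd_pct = if (x$found) x$best$grd_pct else NA_real_
  )
}
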