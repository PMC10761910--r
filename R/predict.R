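# Unified prediction interface for all diameter models, rate prediction by
# conservation of mass, evaluation metrics, and gain-based parameter
# importance.

#' Predict normalized droplet diameter
#'
#' Dispatches on the model class. Besides the fitted models
#' (`scaling_law`, `diameter_nn`, `diameter_trees`, `diameter_consensus`), a
#' plain function of the dataset (returning normalized diameters) is accepted,
#' which is convenient for stub models in tests and oracles.
#'
#' @param model A fitted diameter model or a function `data -> Dbar`.
#' @param data A droplet dataset (outcome columns not required).
#' @return Numeric vector of normalized diameters.
#' @export
predict_norm_diameter <- function(model, data) {
  UseMethod("predict_norm_diameter")
}

#' @export
predict_norm_diameter.scaling_law <- function(model, data) {
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  unname(.scaling_law_value(model$form_id, model$coefficients,
                            d$flow_rate_ratio, d$capillary_number,
                            d$viscosity_ratio))
}

#' @export
predict_norm_diameter.diameter_nn <- function(model, data) {
  x <- as.matrix(featurize(data,
    include_viscosity_ratio = model$spec$include_viscosity_ratio))
  x <- sweep(sweep(x, 2, model$centers), 2, model$scales, `/`)
  as.numeric(.nn_forward(model$weights, x))
}

#' @export
predict_norm_diameter.diameter_trees <- function(model, data) {
  x <- as.matrix(featurize(data,
    include_viscosity_ratio = model$spec$include_viscosity_ratio))
  as.numeric(predict(model$booster, x))
}

#' @export
predict_norm_diameter.diameter_consensus <- function(model, data) {
  consensus_predict(model$nn, model$trees, data)
}

#' @export
predict_norm_diameter.function <- function(model, data) {
  as.numeric(model(data))
}

#' Consensus prediction from two member models
#'
#' Arithmetic mean of the two members' normalized-diameter predictions. By
#' convexity of the absolute error, the consensus pointwise error never
#' exceeds the larger member error.
#'
#' @param nn_model,tree_model The two member models (any class accepted by
#'   [predict_norm_diameter()]).
#' @param data A droplet dataset.
#' @return Numeric vector of normalized diameters.
#' @export
consensus_predict <- function(nn_model, tree_model, data) {
  (predict_norm_diameter(nn_model, data) +
     predict_norm_diameter(tree_model, data)) / 2
}

#' Predict droplet diameter in micrometres
#'
#' Rescales the predicted normalized diameter by the orifice hydraulic
#' diameter of each record.
#'
#' @inheritParams predict_norm_diameter
#' @return Numeric vector of diameters, um.
#' @export
predict_diameter <- function(model, data) {
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  predict_norm_diameter(model, data) * d$hydraulic_diameter_um
}

#' Predict generation rate by conservation of mass
#'
#' Converts the predicted diameter into a generation rate using the dispersed
#' flow rate of each record, `F = 6 * Q_d / (pi * D^3)`. For second-junction
#' (DE_FF2) records the stored dispersed flow is, by construction, the sum of
#' the paired experiment's inner and middle flows. Because the rate scales
#' with the inverse cube of diameter, a small relative diameter error
#' propagates into roughly a three-fold larger relative rate error.
#'
#' @inheritParams predict_norm_diameter
#' @return Numeric vector of rates, Hz.
#' @export
predict_rate <- function(model, data) {
  if (!"dispersed_flow_ulh" %in% names(data)) {
    stop("`data` must carry `dispersed_flow_ulh` to predict rates", call. = FALSE)
  }
  .check_positive(data$dispersed_flow_ulh, "dispersed_flow_ulh")
  generation_rate(data$dispersed_flow_ulh, predict_diameter(model, data))
}

#' Prediction accuracy metrics
#'
#' Mean absolute percentage error (with observed values as denominators),
#' mean absolute error, root-mean-square error and coefficient of
#' determination.
#'
#' @param predictions,truths Equal-length numeric vectors; truths must be
#'   nonzero for the MAPE to be defined.
#' @return A one-row tibble with columns `mape` (percent), `r2`, `mae`,
#'   `rmse` (units of the inputs) and `n`.
#' @examples
#' evaluate(c(27.5, 31.6, 37.9), c(25, 30, 35))
#' @export
evaluate <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) < 1) {
    stop("`predictions` and `truths` must have equal length >= 1", call. = FALSE)
  }
  if (any(truths == 0)) {
    stop("MAPE undefined: `truths` contains zero", call. = FALSE)
  }
  err <- predictions - truths
  ss_tot <- sum((truths - mean(truths))^2)
  tibble::tibble(
    mape = 100 * mean(abs(err) / abs(truths)),
    r2 = 1 - sum(err^2) / ss_tot,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    n = length(truths)
  )
}

#' Gain-based parameter importance across training sessions
#'
#' Trains the boosted-tree model once per randomized session and reports each
#' feature's share of the total loss reduction at the splits where it serves
#' as the decision variable (gain), averaged across sessions; dispersion is
#' two standard deviations. Features a session's ensemble never splits on
#' (e.g. constants) receive a share of zero. Per-session shares sum to one.
#'
#' @param data A droplet dataset.
#' @param spec A [tree_spec()].
#' @param test_fraction,seeds Session-split settings as in [split_sessions()].
#' @return A tibble of class `importance_report` with columns `feature`,
#'   `mean_gain`, `dispersion` (2 sd) and `n_sessions`, ordered by decreasing
#'   mean gain.
#' @export
parameter_importance <- function(data, spec = tree_spec(),
                                 test_fraction = 0.2, seeds = 0:14) {
  sessions <- split_sessions(data, test_fraction, seeds)
  feature_names <- colnames(featurize(data[1, ],
    include_viscosity_ratio = spec$include_viscosity_ratio))
  shares <- vapply(sessions, function(s) {
    model <- fit_diameter_trees(s$train, spec)
    imp <- xgboost::xgb.importance(model = model$booster)
    share <- stats::setNames(rep(0, length(feature_names)), feature_names)
    share[imp$Feature] <- imp$Gain
    share / sum(share)
  }, numeric(length(feature_names)))
  out <- tibble::tibble(
    feature = feature_names,
    mean_gain = rowMeans(shares),
    dispersion = 2 * apply(shares, 1, stats::sd),
    n_sessions = length(sessions)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_gain))
  class(out) <- c("importance_report", class(out))
  out
}
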