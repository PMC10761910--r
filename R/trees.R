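# Gradient-boosted regression trees for normalized droplet diameter, via
# xgboost. Defaults: 100 trees, learning rate 0.3, L2 penalty 1, maximum
# depth 6, leaf splitting halted below a weight of 1, and the 8-feature
# input set (viscosity ratio included). Single-threaded training is
# deterministic: identical data and spec give bit-identical predictions.

#' Boosted-tree specification
#'
#' @param n_trees Number of boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param l2 L2 regularization penalty on leaf weights.
#' @param max_depth Maximum tree depth.
#' @param min_leaf_weight Minimum child weight below which a leaf is not split.
#' @param include_viscosity_ratio Whether the viscosity ratio enters the
#'   feature set (included by default for this model).
#' @param seed RNG seed (training is deterministic single-threaded; the seed
#'   is recorded for provenance).
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(n_trees = 100L, learning_rate = 0.3, l2 = 1,
                      max_depth = 6L, min_leaf_weight = 1,
                      include_viscosity_ratio = TRUE, seed = 0L) {
  structure(list(
    n_trees = as.integer(n_trees), learning_rate = learning_rate, l2 = l2,
    max_depth = as.integer(max_depth), min_leaf_weight = min_leaf_weight,
    include_viscosity_ratio = include_viscosity_ratio, seed = as.integer(seed)
  ), class = "tree_spec")
}

#' Fit the boosted-tree diameter model
#'
#' Trains a gradient-boosted tree ensemble on the dimensionless feature set
#' to predict normalized droplet diameter under squared-error loss.
#'
#' @param data A droplet dataset.
#' @param spec A [tree_spec()].
#' @return An object of class `diameter_trees`.
#' @export
fit_diameter_trees <- function(data, spec = tree_spec()) {
  stopifnot(inherits(spec, "tree_spec"))
  feats <- featurize(data, include_viscosity_ratio = spec$include_viscosity_ratio)
  x <- as.matrix(feats)
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  y <- d$norm_diameter
  if (nrow(x) == 0) stop("training data is empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite feature or target values", call. = FALSE)
  }
  booster <- withr::with_seed(spec$seed, {
    dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    params <- xgboost::xgb.params(
      objective = "reg:squarederror",
      learning_rate = spec$learning_rate,
      reg_lambda = spec$l2,
      max_depth = spec$max_depth,
      min_child_weight = spec$min_leaf_weight,
      nthread = 1,
      seed = spec$seed
    )
    xgboost::xgb.train(params, dm, nrounds = spec$n_trees, verbose = 0)
  })
  structure(list(
    booster = booster, features = colnames(feats), spec = spec, n = nrow(x)
  ), class = "diameter_trees")
}

#' @export
print.diameter_trees <- function(x, ...) {
  cat("Boosted-tree diameter model:", length(x$features), "features,",
      x$spec$n_trees, "trees (depth <=", x$spec$max_depth, ")\n")
  cat("trained on", x$n, "records\n")
  invisible(x)
}

#' Consensus diameter model
#'
#' Averages the normalized-diameter predictions of the neural network and the
#' boosted trees (arithmetic mean of diameters). The consensus combines the
#' trees' accuracy on rate prediction with the network's accuracy on
#' double-emulsion stability.
#'
#' @param nn_model A `diameter_nn` model.
#' @param tree_model A `diameter_trees` model.
#' @return An object of class `diameter_consensus`.
#' @export
consensus_model <- function(nn_model, tree_model) {
  stopifnot(inherits(nn_model, "diameter_nn"),
            inherits(tree_model, "diameter_trees"))
  structure(list(nn = nn_model, trees = tree_model),
            class = "diameter_consensus")
}

#' @export
print.diameter_consensus <- function(x, ...) {
  cat("Consensus diameter model (mean of neural network and boosted trees)\n")
  invisible(x)
}

#' Train the full consensus predictor in one call
#'
#' Convenience wrapper fitting the neural network and boosted trees on the
#' same data and returning their consensus.
#'
#' @param data A droplet dataset.
#' @param nn A [nn_spec()].
#' @param trees A [tree_spec()].
#' @return A `diameter_consensus` model.
#' @export
fit_consensus <- function(data, nn = nn_spec(), trees = tree_spec()) {
  consensus_model(fit_diameter_nn(data, nn), fit_diameter_trees(data, trees))
}
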