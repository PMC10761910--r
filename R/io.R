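# Model persistence: a model directory holds human-readable JSON metadata
# (class, featurization, spec, seeds) next to natively serialized weights.

#' Save a fitted diameter model to a directory
#'
#' Writes `metadata.json` describing the model plus its native weights:
#' scaling-law coefficients live entirely in the JSON; the neural network
#' serializes its weight matrices; the boosted trees use the xgboost native
#' format. Consensus models save both members in subdirectories.
#'
#' @param model A fitted `scaling_law`, `diameter_nn`, `diameter_trees` or
#'   `diameter_consensus` model.
#' @param path Directory to create (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "dropletdesign", class = class(model)[1])
  if (inherits(model, "scaling_law")) {
    meta$form_id <- model$form_id
    meta$coefficients <- as.list(model$coefficients)
    meta$n <- model$n
    meta$training_mape <- model$training_mape
  } else if (inherits(model, "diameter_nn")) {
    meta$spec <- unclass(model$spec)
    meta$features <- model$features
    meta$best_epoch <- model$best_epoch
    saveRDS(model[c("weights", "centers", "scales", "history", "val_loss", "n")],
            file.path(path, "weights.rds"))
  } else if (inherits(model, "diameter_trees")) {
    meta$spec <- unclass(model$spec)
    meta$features <- model$features
    meta$n <- model$n
    xgboost::xgb.save(model$booster, file.path(path, "trees.ubj"))
  } else if (inherits(model, "diameter_consensus")) {
    save_model(model$nn, file.path(path, "nn"))
    save_model(model$trees, file.path(path, "trees"))
  } else {
    stop("unsupported model class: ", class(model)[1], call. = FALSE)
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a fitted diameter model from a directory
#'
#' @param path A directory written by [save_model()].
#' @return The restored model object.
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  switch(meta$class,
    scaling_law = {
      # refit container without the lm object; predictions only need the
      # coefficients and form
      structure(list(form_id = meta$form_id,
                     coefficients = unlist(meta$coefficients),
                     n = meta$n, training_mape = meta$training_mape),
                class = "scaling_law")
    },
    diameter_nn = {
      bits <- readRDS(file.path(path, "weights.rds"))
      spec <- do.call(nn_spec, meta$spec[setdiff(names(meta$spec), NULL)])
      structure(c(bits, list(features = meta$features, spec = spec,
                             best_epoch = meta$best_epoch)),
                class = "diameter_nn")
    },
    diameter_trees = {
      spec <- do.call(tree_spec, meta$spec)
      structure(list(booster = xgboost::xgb.load(file.path(path, "trees.ubj")),
                     features = meta$features, spec = spec, n = meta$n),
                class = "diameter_trees")
    },
    diameter_consensus = consensus_model(load_model(file.path(path, "nn")),
                                         load_model(file.path(path, "trees"))),
    stop("unknown model class in metadata: ", meta$class, call. = FALSE)
  )
}
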