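# Shared fixtures: all built in code at test time.

# noise-free ground-truth law used as an oracle model in design/stability tests
oracle_law <- truth_law(noise_sd = 0)

# a diameter "model" that evaluates the ground-truth law exactly
oracle_model <- function(law = oracle_law) {
  function(data) {
    d <- derive_features(data)
    law_norm_diameter(law, d$flow_rate_ratio, d$capillary_number,
                      d$viscosity_ratio, d$norm_channel_depth)
  }
}

# a stub model predicting a constant normalized diameter
constant_model <- function(dbar) function(data) rep(dbar, nrow(data))

# session-level caches so expensive fits are shared across test files
.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function() {
  if (is.null(.fixture_env$data)) {
    .fixture_env$data <- generate_droplets(
      synthetic_config(n_records = 868, seed = 42))
  }
  .fixture_env$data
}

fixture_consensus <- function() {
  if (is.null(.fixture_env$consensus)) {
    .fixture_env$consensus <- fit_consensus(
      fixture_dataset(),
      nn = nn_spec(max_epochs = 300, seed = 7),
      trees = tree_spec(seed = 7))
  }
  .fixture_env$consensus
}

# small single-junction geometry + fluids for stability tests
fixture_de_config <- function(q_inner = 200, q_middle = 500, q_outer = 4000) {
  ff1 <- flow_focuser(22.5, 22.5, 22.5, 22.5, 22.5)
  ff2 <- flow_focuser(45, 45, 45, 45, 45)
  de_config(ff1, ff2,
            fluid_phase("inner", 1.0), fluid_phase("middle", 1.6),
            fluid_phase("outer", 1.3),
            ift_inner_middle = 5, ift_middle_outer = 3,
            q_inner = q_inner, q_middle = q_middle, q_outer = q_outer)
}
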