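test_that("evaluate computes the four accuracy metrics", {
  m <- evaluate(c(27.5, 31.6, 37.9), c(25, 30, 35))
  expect_equal(round(m$mae, 1), 2.3)
  expect_equal(round(m$mape, 1), 7.9)
  perfect <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mape, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  # predicting the mean gives R^2 = 0 by definition
  truths <- c(10, 20, 30)
  expect_equal(evaluate(rep(mean(truths), 3), truths)$r2, 0)
  expect_error(evaluate(c(1, 2), c(1, 0)), "zero")
  expect_error(evaluate(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("boosted trees interpolate the synthetic law and are deterministic", {
  d <- fixture_dataset()
  s <- split_sessions(d, seeds = 0)[[1]]
  m1 <- fit_diameter_trees(s$train, tree_spec(seed = 1))
  m2 <- fit_diameter_trees(s$train, tree_spec(seed = 1))
  p1 <- predict_diameter(m1, s$test)
  expect_identical(p1, predict_diameter(m2, s$test))
  expect_true(all(p1 > 0))
  expect_lt(evaluate(p1, s$test$diameter_um)$mape, 5)
})

test_that("the neural network learns the synthetic law reproducibly", {
  d <- fixture_dataset()
  s <- split_sessions(d, seeds = 0)[[1]]
  nn <- fixture_consensus()$nn
  p <- predict_diameter(nn, s$test)
  expect_true(all(p > 0))
  expect_lt(evaluate(p, s$test$diameter_um)$mape, 10)
  # same seed and data reproduce training to numerical tolerance (training
  # is single-threaded and fully seeded, so this is exact)
  nn2 <- fit_diameter_nn(d, nn_spec(max_epochs = 5, seed = 3))
  nn3 <- fit_diameter_nn(d, nn_spec(max_epochs = 5, seed = 3))
  expect_equal(predict_norm_diameter(nn2, s$test),
               predict_norm_diameter(nn3, s$test), tolerance = 1e-12)
})

test_that("consensus is the arithmetic mean and never the worst member", {
  d <- fixture_dataset()
  s <- split_sessions(d, seeds = 1)[[1]]
  cm <- fixture_consensus()
  p_nn <- predict_norm_diameter(cm$nn, s$test)
  p_tr <- predict_norm_diameter(cm$trees, s$test)
  p_cm <- predict_norm_diameter(cm, s$test)
  expect_equal(p_cm, (p_nn + p_tr) / 2)
  expect_equal(consensus_predict(constant_model(1.0), constant_model(1.2),
                                 s$test[1, ]), 1.1)
  # pointwise: consensus absolute error <= max member absolute error
  truth <- s$test$norm_diameter
  expect_true(all(abs(p_cm - truth) <=
                    pmax(abs(p_nn - truth), abs(p_tr - truth)) + 1e-12))
  # in aggregate: consensus MAPE <= mean of member MAPEs
  mape <- function(p) evaluate(p, truth)$mape
  expect_lte(mape(p_cm), (mape(p_nn) + mape(p_tr)) / 2 + 1e-9)
})

test_that("rate predictions amplify diameter errors about three-fold", {
  # conservation of mass makes rate scale as the inverse cube of diameter,
  # so small iid relative diameter errors triple in the rate MAPE
  set.seed(21)
  n <- 5000
  d_true <- runif(n, 20, 200)
  q <- runif(n, 10, 1000)
  d_pred <- d_true * (1 + rnorm(n, 0, 0.02))
  f_true <- generation_rate(q, d_true)
  f_pred <- generation_rate(q, d_pred)
  ratio <- evaluate(f_pred, f_true)$mape / evaluate(d_pred, d_true)$mape
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 3.2)
})

test_that("rate prediction uses the stored dispersed flow", {
  # a model pinning the normalized diameter to 1 on a 100 um square orifice
  # with Q_d chosen as one droplet volume per second gives 1 Hz
  row <- tibble::tibble(
    emulsion_class = "SE", orifice_width_um = 100, channel_depth_um = 100,
    dispersed_inlet_width_um = 100, continuous_inlet_width_um = 100,
    outlet_width_um = 100, dispersed_viscosity_mPas = 1,
    continuous_viscosity_mPas = 10, interfacial_tension_mNm = 5,
    continuous_flow_ulh = 100, dispersed_flow_ulh = pi / 6 * 1e6 * 3600e-9)
  expect_equal(predict_rate(constant_model(1), row), 1.0, tolerance = 1e-12)
  expect_error(predict_rate(constant_model(1),
                            dplyr::select(row, -"dispersed_flow_ulh")),
               "dispersed_flow_ulh")
})

test_that("gain importance concentrates on the truly informative input", {
  # diameter depends only on the flow-rate ratio: it must take the top share
  law <- truth_law(a = 1, b = -0.4, c = 0, d = 0, noise_sd = 0.01)
  d <- generate_droplets(synthetic_config(n_records = 400, seed = 22), law)
  imp <- parameter_importance(d, tree_spec(), seeds = 0:2)
  expect_equal(imp$feature[1], "flow_rate_ratio")
  expect_gt(imp$mean_gain[1], 0.5)
  # shares sum to one within numerical tolerance
  expect_equal(sum(imp$mean_gain), 1, tolerance = 1e-9)
  # a constant feature is never split on
  d2 <- d
  d2$channel_depth_um <- d2$orifice_width_um # norm depth constant at 1
  d2 <- d2[setdiff(names(d2), "norm_channel_depth")]
  imp2 <- parameter_importance(d2, tree_spec(), seeds = 0:2)
  expect_equal(unname(imp2$mean_gain[imp2$feature == "norm_channel_depth"]), 0)
})

test_that("training rejects degenerate inputs", {
  d <- fixture_dataset()[0, ]
  expect_error(fit_diameter_trees(d), "empty")
  expect_error(fit_diameter_nn(d), "empty")
})
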