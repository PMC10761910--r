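se_request <- function(diameter = 50, rate = NULL, constraints = list()) {
  design_request(diameter = diameter, rate = rate,
                 dispersed_viscosity = 1, continuous_viscosity = 5,
                 interfacial_tension = 5, constraints = constraints)
}

test_that("the design cost is zero iff the request is met in each dimension", {
  req <- se_request(diameter = 50, rate = 100)
  expect_equal(design_cost(50, 100, req), 0)
  expect_gt(design_cost(51, 100, req), 0)
  expect_gt(design_cost(50, 101, req), 0)
  # unspecified targets are dropped from the cost
  req_d <- se_request(diameter = 50)
  expect_equal(design_cost(50, 12345, req_d), 0)
  # scalar normalization: 25 um of diameter error weighs like 1200 Hz of rate
  expect_equal(design_cost(75, 100, req), design_cost(50, 1300, req))
})

test_that("the nearest experimental point short-circuits matching requests", {
  d <- fixture_dataset()
  rec <- derive_features(d[setdiff(names(d), "norm_diameter")])[17, ]
  # request exactly matching a record: that record, zero cost
  req <- se_request(diameter = rec$diameter_um, rate = rec$rate_hz)
  sol <- nearest_experimental_point(req, d)
  expect_s3_class(sol, "design_solution")
  expect_equal(sol$cost, 0)
  expect_equal(sol$provenance, "experimental_point")
  expect_equal(sol$predicted_diameter_um, rec$diameter_um)
  # a request within 2 um and 10 Hz still returns the record
  req2 <- se_request(diameter = rec$diameter_um + 2,
                     rate = max(rec$rate_hz - 10, 5.5))
  expect_s3_class(nearest_experimental_point(req2, d), "design_solution")
  # far from every record: nothing
  far <- d$diameter_um + 10
  req3 <- se_request(diameter = rec$diameter_um)
  d_far <- d
  d_far$diameter_um <- far
  expect_null(nearest_experimental_point(se_request(diameter = 16), d_far[abs(far - 16) > 10, ]))
})

test_that("constraints restrict admissible experimental points", {
  d <- fixture_dataset()
  rec <- d[5, ]
  req <- se_request(diameter = rec$diameter_um,
                    constraints = list(orifice_width_um = c(150, 175)))
  sol <- nearest_experimental_point(req, d)
  if (!is.null(sol)) {
    expect_gte(sol$geometry$orifice_width_um, 150)
  }
  # fixed constraint admitting no record
  req2 <- se_request(diameter = rec$diameter_um,
                     constraints = list(orifice_width_um = 1234))
  expect_null(nearest_experimental_point(req2, d))
})

test_that("coordinate-descent design hits a diameter target on the oracle", {
  m <- oracle_model()
  sol <- design_se(se_request(diameter = 50), m)
  expect_true(sol$converged)
  expect_lt(abs(sol$predicted_diameter_um - 50), 0.5)
  # the recorded cost trace is non-increasing
  expect_true(all(diff(sol$trace$cost) <= 0))
  # flows are consistent with the returned Ca and flow ratio
  expect_equal(
    continuous_flow_from_capillary(sol$capillary_number, 5,
                                   sol$geometry$orifice_width_um,
                                   sol$geometry$channel_depth_um, 5),
    sol$continuous_flow_ulh, tolerance = 1e-9)
  expect_equal(sol$continuous_flow_ulh / sol$flow_rate_ratio,
               sol$dispersed_flow_ulh, tolerance = 1e-9)
})

test_that("design respects fixed constraints and bound boxes", {
  m <- oracle_model()
  sol <- design_se(se_request(diameter = 40, constraints = list(
    orifice_width_um = 30, norm_channel_depth = c(1, 2))), m)
  expect_equal(sol$geometry$orifice_width_um, 30)
  expect_lte(sol$geometry$channel_depth_um / 30, 2)
  expect_gte(sol$geometry$channel_depth_um / 30, 1)
  # all parameters fixed: the single admissible design is evaluated once
  all_fixed <- list(orifice_width_um = 50, norm_channel_depth = 2,
                    norm_dispersed_inlet = 2, norm_continuous_inlet = 2,
                    norm_outlet = 3, capillary_number = 0.5,
                    flow_rate_ratio = 5)
  sol2 <- design_se(se_request(diameter = 40, constraints = all_fixed), m)
  expect_equal(sol2$iterations, 0)
  expect_equal(sol2$geometry$orifice_width_um, 50)
  expect_equal(sol2$capillary_number, 0.5, tolerance = 1e-12)
})

test_that("requests outside the supported output range are infeasible", {
  m <- oracle_model()
  expect_error(design_se(se_request(diameter = 500), m), "infeasible")
  expect_error(design_se(se_request(diameter = NULL, rate = 2e5), m),
               "infeasible")
})

test_that("the performance heat map sweeps +-25% around the design", {
  m <- oracle_model()
  sol <- design_se(se_request(diameter = 60), m)
  hm <- performance_heatmap(sol, m, span = 0.25, n = 5)
  expect_equal(nrow(hm), 25)
  center <- hm[hm$is_center, ]
  expect_equal(nrow(center), 1)
  expect_equal(center$diameter_um, sol$predicted_diameter_um, tolerance = 1e-9)
  expect_equal(range(hm$q_d_ulh),
               sol$dispersed_flow_ulh * c(0.75, 1.25), tolerance = 1e-12)
  # at fixed predicted normalized diameter the rate grows with dispersed flow
  hm2 <- performance_heatmap(sol, constant_model(1), n = 5)
  for (grp in split(hm2, hm2$q_c_ulh)) {
    expect_true(all(diff(grp$rate_hz[order(grp$q_d_ulh)]) > 0))
  }
})

test_that("double-emulsion design filters by GRD and ranks by diameter error", {
  m <- oracle_model()
  req <- de_design_request(20, 40, fluid_phase("i", 1), fluid_phase("m", 1.6),
                           fluid_phase("o", 1.3), 5, 3)
  dd <- design_de(req, m, q_inner = seq(50, 650, by = 100),
                  q_middle = seq(200, 1200, by = 200),
                  q_outer = seq(1500, 10000, by = 500))
  expect_true(dd$found)
  expect_true(all(abs(dd$solutions$grd_pct) < 5))
  # conservation of mass in every returned solution
  expect_equal(dd$solutions$q_total_ulh,
               dd$solutions$q_inner_ulh + dd$solutions$q_middle_ulh)
  # ranked ascending by error; the oracle-evaluated error of the top-ranked
  # solution is no worse than any lower-ranked one
  expect_true(!is.unsorted(dd$solutions$error_pct))
  expect_equal(dd$best$error_pct, min(dd$solutions$error_pct))
  # rate columns recompute from the predicted diameters
  expect_equal(dd$best$rate_ff2_hz,
               generation_rate(dd$best$q_total_ulh, dd$best$outer_diameter_um))
})

test_that("an impossible GRD filter yields an explicit no-solution result", {
  # stub model: FF1 always much faster than FF2
  stub <- function(data) ifelse(data$emulsion_class == "DE_FF1", 0.4, 1.8)
  req <- de_design_request(20, 40, fluid_phase("i", 1), fluid_phase("m", 1.6),
                           fluid_phase("o", 1.3), 5, 3)
  dd <- design_de(req, stub, q_inner = c(100, 300), q_middle = c(400, 800),
                  q_outer = c(2000, 6000))
  expect_false(dd$found)
  expect_null(dd$best)
  expect_equal(nrow(dd$solutions), 0)
  expect_output(print(dd), "no solution")
})

test_that("custom device pairs are accepted for DE design", {
  m <- oracle_model()
  req <- de_design_request(25, 45, fluid_phase("i", 1), fluid_phase("m", 1.6),
                           fluid_phase("o", 1.3), 5, 3)
  custom <- list(ff1 = flow_focuser(22.5, 22.5, 22.5, 22.5, 22.5),
                 ff2 = flow_focuser(45, 45, 45, 45, 45))
  dd <- design_de(req, m, devices = custom,
                  q_inner = seq(100, 600, by = 100),
                  q_middle = seq(200, 1200, by = 200),
                  q_outer = seq(1500, 9500, by = 1000))
  expect_true(all(dd$solutions$device_id == "custom"))
})
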