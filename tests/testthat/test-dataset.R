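test_that("CSV round trip preserves raw fields and derived fields recompute", {
  d <- generate_droplets(synthetic_config(n_records = 50, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_droplets(d, path)
  d2 <- read_droplets(path)
  raw_cols <- setdiff(intersect(names(d), names(d2)),
                      c("record_id", "source_tag", "emulsion_class"))
  numeric_raw <- raw_cols[!grepl("^(norm_|capillary|flow_rate|viscosity_ratio|hydraulic)", raw_cols)]
  for (col in numeric_raw) expect_identical(d2[[col]], d[[col]])
  for (col in c("capillary_number", "flow_rate_ratio", "viscosity_ratio",
                "norm_diameter")) {
    expect_equal(d2[[col]], d[[col]], tolerance = 1e-12)
  }
  expect_equal(attr(d2, "load_report")$n_out_of_envelope, 0)
})

test_that("schema violations are rejected with informative errors", {
  d <- generate_droplets(synthetic_config(n_records = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_droplets(dplyr::select(d, -"orifice_width_um"), path)
  expect_error(read_droplets(path), "orifice_width_um")

  d_bad <- d
  d_bad$diameter_um <- as.character(d_bad$diameter_um)
  d_bad$diameter_um[3] <- "not-a-number"
  write_droplets(d_bad, path)
  expect_error(read_droplets(path), "diameter_um")
})

test_that("out-of-envelope records load with a warning, not rejection", {
  d <- generate_droplets(synthetic_config(n_records = 5, seed = 3))
  # push one record far outside the capillary-number envelope
  d$continuous_flow_ulh[1] <- d$continuous_flow_ulh[1] * 1e3
  path <- withr::local_tempfile(fileext = ".csv")
  write_droplets(dplyr::select(d, -dplyr::all_of(
    c("capillary_number", "flow_rate_ratio", "viscosity_ratio",
      "norm_diameter", "norm_channel_depth", "norm_dispersed_inlet",
      "norm_continuous_inlet", "norm_outlet", "hydraulic_diameter_um"))), path)
  d2 <- suppressWarnings(read_droplets(path))
  expect_equal(nrow(d2), 5)
  rep <- attr(d2, "load_report")
  expect_gte(rep$n_out_of_envelope, 1)
  expect_match(rep$warnings, "capillary_number", all = FALSE)
})

test_that("stored derived values disagreeing with raw fields are flagged", {
  d <- generate_droplets(synthetic_config(n_records = 5, seed = 4))
  d$capillary_number[2] <- d$capillary_number[2] * 1.5
  rep <- validate_droplets(d)
  expect_gte(rep$n_derived_mismatch, 1)
  expect_match(rep$warnings, "capillary_number", all = FALSE)
})

test_that("double-emulsion expansion builds two junction records", {
  inner <- fluid_phase("aqueous", 1.0)
  middle <- fluid_phase("oil", 1.61)
  outer <- fluid_phase("sheath", 1.303)
  g1 <- flow_focuser(22.5, 22.5, 22.5, 22.5, 22.5)
  g2 <- flow_focuser(45, 45, 45, 45, 45)
  pair <- expand_de_experiment(inner, middle, outer, g1, g2,
                               ift_inner_middle = 12.84,
                               ift_middle_outer = 0.318,
                               q_inner = 100, q_middle = 400, q_outer = 4000,
                               inner_diameter = 25, outer_diameter = 48)
  expect_equal(nrow(pair), 2)
  expect_equal(pair$emulsion_class, c("DE_FF1", "DE_FF2"))
  # conservation of mass: FF2 dispersed flow is the exact total of FF1 flows
  expect_identical(pair$dispersed_flow_ulh[2], 100 + 400)
  expect_equal(pair$flow_rate_ratio[2], 4000 / 500)
  # each junction sees its own phase pair
  expect_equal(pair$viscosity_ratio[1], 1.61 / 1.0)
  expect_equal(pair$viscosity_ratio[2], 1.303 / 1.61)
  # diameters normalized by each junction's own hydraulic diameter
  expect_equal(pair$norm_diameter, c(25 / 22.5, 48 / 45))
  # rates follow from the observed diameters by conservation of mass
  expect_equal(pair$rate_hz, generation_rate(c(100, 500), c(25, 48)))
  expect_error(expand_de_experiment(inner, middle, outer, g1, g2, 1, 1,
                                    -5, 400, 4000, 25, 48), "q_inner")
})

test_that("featurization yields the documented feature sets in order", {
  d <- generate_droplets(synthetic_config(n_records = 10, seed = 5))
  f8 <- featurize(d, include_viscosity_ratio = TRUE)
  f7 <- featurize(d, include_viscosity_ratio = FALSE)
  expect_equal(ncol(f8), 8)
  expect_equal(ncol(f7), 7)
  expect_equal(names(f8),
               c("orifice_width_um", "viscosity_ratio", "capillary_number",
                 "flow_rate_ratio", "norm_channel_depth",
                 "norm_dispersed_inlet", "norm_continuous_inlet",
                 "norm_outlet"))
  expect_false("viscosity_ratio" %in% names(f7))
  # a square-orifice device with all widths equal to the orifice has unit
  # normalized geometry
  row <- tibble::tibble(
    emulsion_class = "SE", orifice_width_um = 22.5, channel_depth_um = 22.5,
    dispersed_inlet_width_um = 22.5, continuous_inlet_width_um = 22.5,
    outlet_width_um = 22.5, dispersed_viscosity_mPas = 1,
    continuous_viscosity_mPas = 1.6, interfacial_tension_mNm = 5,
    continuous_flow_ulh = 100, dispersed_flow_ulh = 10,
    diameter_um = 25, rate_hz = 100)
  f <- featurize(row)
  expect_equal(unlist(f[1, c("norm_channel_depth", "norm_dispersed_inlet",
                             "norm_continuous_inlet", "norm_outlet")]),
               c(norm_channel_depth = 1, norm_dispersed_inlet = 1,
                 norm_continuous_inlet = 1, norm_outlet = 1))
})

test_that("session splits are disjoint, exhaustive and reproducible", {
  d <- generate_droplets(synthetic_config(n_records = 868, seed = 6))
  splits <- split_sessions(d, test_fraction = 0.2, seeds = 0:2)
  expect_length(splits, 3)
  s <- splits[[1]]
  expect_equal(nrow(s$test), 173) # floor(0.2 * 868)
  expect_equal(nrow(s$train), 695)
  key <- function(x) paste(x$record_id)
  expect_length(intersect(key(s$train), key(s$test)), 0)
  expect_setequal(c(key(s$train), key(s$test)), key(d))
  splits2 <- split_sessions(d, test_fraction = 0.2, seeds = 0:2)
  expect_identical(key(splits2[[1]]$test), key(s$test))
  expect_error(split_sessions(d[1:3, ]), "at least 5")
  expect_error(split_sessions(d, seeds = c(1, 1)), "distinct")
})
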