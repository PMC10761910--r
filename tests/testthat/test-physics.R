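test_that("hydraulic diameter matches the rectangular-duct formula", {
  expect_equal(hydraulic_diameter(22.5, 22.5), 22.5)
  expect_equal(hydraulic_diameter(175, 175), 175)
  expect_equal(hydraulic_diameter(30, 40), 2400 / 70)
  expect_error(hydraulic_diameter(-1, 10), "orifice_width")
  expect_error(hydraulic_diameter(10, 0), "channel_depth")
})

test_that("capillary number converts units correctly and is linear in viscosity", {
  # DI water / mineral-oil pair: mu_c 57.2 mPa.s, sigma 5 mN/m, square 100 um
  # orifice at 360 uL/h gives U_c = 0.01 m/s and Ca = 0.1144
  expect_equal(continuous_orifice_velocity(360, 100, 100), 0.01)
  expect_equal(capillary_number(57.2, 5, 360, 100, 100), 0.1144)
  expect_equal(capillary_number(2 * 57.2, 5, 360, 100, 100), 2 * 0.1144)
  expect_error(capillary_number(57.2, 0, 360, 100, 100), "interfacial_tension")
})

test_that("capillary number is invariant under consistent geometric rescaling", {
  # Ca is dimensionless: rescaling the device by s while scaling the flow by
  # s^2 keeps the orifice velocity, and hence Ca, unchanged
  set.seed(11)
  for (i in 1:20) {
    mu <- runif(1, 1, 60); sig <- runif(1, 0.3, 13)
    q <- runif(1, 50, 5000); w <- runif(1, 15, 175); h <- runif(1, 15, 400)
    s <- runif(1, 0.1, 10)
    ca1 <- capillary_number(mu, sig, q, w, h)
    ca2 <- capillary_number(mu, sig, q * s^2, w * s, h * s)
    expect_equal(ca2, ca1, tolerance = 1e-12)
  }
})

test_that("continuous flow from capillary number inverts the forward map", {
  expect_equal(continuous_flow_from_capillary(0.1144, 5, 100, 100, 57.2), 360)
  # doubling the orifice cross-section doubles the flow at fixed Ca
  expect_equal(continuous_flow_from_capillary(0.1144, 5, 200, 100, 57.2),
               2 * 360)
  set.seed(12)
  for (i in 1:50) {
    mu <- runif(1, 0.8, 60); sig <- runif(1, 0.3, 13)
    w <- runif(1, 15, 175); h <- runif(1, 15, 400); ca <- runif(1, 0.01, 10)
    q <- continuous_flow_from_capillary(ca, sig, w, h, mu)
    expect_equal(capillary_number(mu, sig, q, w, h), ca, tolerance = 1e-12)
  }
})

test_that("dispersed flow follows from the flow-rate ratio", {
  expect_equal(dispersed_flow_from_ratio(360, 10), 36)
  expect_equal(dispersed_flow_from_ratio(360, 1), 360)
  expect_equal(dispersed_flow_from_ratio(100, 0.69), 100 / 0.69,
               tolerance = 1e-9)
  expect_error(dispersed_flow_from_ratio(100, 0), "flow_rate_ratio")
})

test_that("generation rate conserves mass", {
  expect_equal(generation_rate(1.885, 100), 1.0, tolerance = 1e-4)
  # halving the diameter multiplies the rate by 8
  expect_equal(generation_rate(10, 50), 8 * generation_rate(10, 100))
  set.seed(13)
  q <- runif(1000, 0.5, 5000)
  d <- runif(1000, 15, 250)
  f <- generation_rate(q, d)
  expect_equal(f * droplet_volume(d) * 3600, q, tolerance = 1e-9)
  # inverse map recovers the diameter
  expect_equal(diameter_from_rate(q, f), d, tolerance = 1e-12)
})

test_that("normalized diameter rescales exactly by the hydraulic diameter", {
  set.seed(14)
  w <- runif(50, 15, 175); h <- runif(50, 15, 400); d <- runif(50, 10, 250)
  dh <- hydraulic_diameter(w, h)
  expect_equal((d / dh) * dh, d, tolerance = 1e-14)
})

test_that("viscosity ratio is the continuous-to-dispersed quotient", {
  expect_equal(viscosity_ratio(57.2, 1.001), 57.2 / 1.001)
  expect_equal(round(viscosity_ratio(57.2, 1.001), 2), 57.14)
  expect_equal(viscosity_ratio(3, 3), 1)
  expect_equal(round(viscosity_ratio(1.61, 3.431), 3), 0.469)
})

test_that("Good-Girifalco interfacial tension behaves at its closed forms", {
  # identical phases interact fully: zero interfacial tension
  expect_equal(good_girifalco_ift(30, 30, 50, 50), 0)
  # equal molar volumes reduce to (sqrt(s_c) - sqrt(s_d))^2
  expect_equal(good_girifalco_ift(72, 18, 18, 18), (sqrt(72) - sqrt(18))^2)
  # V_c = 4 V_d gives an interaction coefficient of 8/9
  s <- good_girifalco_ift(50, 50, 40, 10)
  expect_equal(s, 2 * 50 - 2 * (8 / 9) * 50)
  # legacy unsquared denominator reproduces the non-dimensionless variant
  phi_legacy <- 4 * sqrt(0.04 * 0.01) / (sqrt(0.04) + sqrt(0.01))
  expect_equal(
    good_girifalco_ift(50, 50, 0.04, 0.01, squared_denominator = FALSE),
    100 - 2 * phi_legacy * 50)
  expect_error(good_girifalco_ift(30, 30, NA, 50), "insufficient fluid data")
  # coefficient > 1 would give negative tension for similar fluids: error,
  # never a silent clamp (legacy form with large volumes exceeds 1)
  expect_error(
    good_girifalco_ift(30, 30, 100, 100, squared_denominator = FALSE),
    "validity range")
})
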