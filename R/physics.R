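# Closed-form relations for flow-focusing droplet generation.
#
# Canonical units throughout the package: lengths in um, dynamic viscosity in
# mPa.s, interfacial/surface tension in mN/m, volumetric flow in uL/h,
# generation rate in Hz, molar volume in cm^3/mol. Every operation converts to
# SI internally before forming a dimensionless ratio; no smoothing, clamping,
# or silent unit inference is applied.

# uL/h -> m^3/s
.UL_H_TO_M3_S <- 1e-9 / 3600
# uL/h -> um^3/s
.UL_H_TO_UM3_S <- 1e9 / 3600

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop("`", name, "` must be a positive finite number", call. = FALSE)
  }
  invisible(x)
}

#' Hydraulic diameter of a rectangular orifice
#'
#' The equivalent circular diameter of the rectangular orifice cross-section,
#' `2 * W_or * H / (W_or + H)`, used to nondimensionalize droplet diameters.
#' For a square duct (`W_or == H`) it equals the side length.
#'
#' @param orifice_width Orifice width `W_or` in micrometres.
#' @param channel_depth Channel depth `H` in micrometres.
#' @return Hydraulic diameter in micrometres.
#' @examples
#' hydraulic_diameter(22.5, 22.5)
#' hydraulic_diameter(30, 40)
#' @export
hydraulic_diameter <- function(orifice_width, channel_depth) {
  .check_positive(orifice_width, "orifice_width")
  .check_positive(channel_depth, "channel_depth")
  2 * orifice_width * channel_depth / (orifice_width + channel_depth)
}

#' Mean continuous-phase velocity through the orifice
#'
#' Volumetric flow of the continuous fluid divided by the orifice
#' cross-sectional area.
#'
#' @param continuous_flow Continuous-phase flow rate in uL/h.
#' @inheritParams hydraulic_diameter
#' @return Velocity in m/s.
#' @export
continuous_orifice_velocity <- function(continuous_flow, orifice_width, channel_depth) {
  .check_positive(continuous_flow, "continuous_flow")
  .check_positive(orifice_width, "orifice_width")
  .check_positive(channel_depth, "channel_depth")
  (continuous_flow * .UL_H_TO_M3_S) / (orifice_width * channel_depth * 1e-12)
}

#' Capillary number of the continuous phase
#'
#' Ratio of the viscous stress exerted by the continuous fluid to the
#' interfacial tension resisting pinch-off: `Ca = mu_c * U_c / sigma`, with
#' `U_c` the mean continuous-phase velocity through the orifice. All inputs are
#' converted to SI before the ratio is formed.
#'
#' @param continuous_viscosity Continuous-phase dynamic viscosity, mPa.s.
#' @param interfacial_tension Interfacial tension between the phases, mN/m.
#' @param continuous_flow Continuous-phase flow rate, uL/h.
#' @inheritParams hydraulic_diameter
#' @return Dimensionless capillary number.
#' @examples
#' capillary_number(57.2, 5, 360, 100, 100) # 0.1144
#' @export
capillary_number <- function(continuous_viscosity, interfacial_tension,
                             continuous_flow, orifice_width, channel_depth) {
  .check_positive(continuous_viscosity, "continuous_viscosity")
  .check_positive(interfacial_tension, "interfacial_tension")
  u <- continuous_orifice_velocity(continuous_flow, orifice_width, channel_depth)
  (continuous_viscosity * 1e-3) * u / (interfacial_tension * 1e-3)
}

#' Continuous flow rate that realizes a target capillary number
#'
#' Exact algebraic inverse of [capillary_number()]:
#' `Q_c = Ca * sigma * W_or * H / mu_c` (with unit conversions).
#'
#' @param ca Target capillary number (dimensionless).
#' @inheritParams capillary_number
#' @return Continuous-phase flow rate in uL/h.
#' @examples
#' continuous_flow_from_capillary(0.1144, 5, 100, 100, 57.2) # 360 uL/h
#' @export
continuous_flow_from_capillary <- function(ca, interfacial_tension,
                                           orifice_width, channel_depth,
                                           continuous_viscosity) {
  .check_positive(ca, "ca")
  .check_positive(interfacial_tension, "interfacial_tension")
  .check_positive(orifice_width, "orifice_width")
  .check_positive(channel_depth, "channel_depth")
  .check_positive(continuous_viscosity, "continuous_viscosity")
  u <- ca * (interfacial_tension * 1e-3) / (continuous_viscosity * 1e-3) # m/s
  u * (orifice_width * channel_depth * 1e-12) / .UL_H_TO_M3_S
}

#' Dispersed flow rate from the flow-rate ratio
#'
#' `Q_d = Q_c / Phi`, where `Phi` is the continuous-to-dispersed flow-rate
#' ratio.
#'
#' @inheritParams capillary_number
#' @param flow_rate_ratio Continuous-to-dispersed flow-rate ratio, dimensionless.
#' @return Dispersed-phase flow rate in uL/h.
#' @export
dispersed_flow_from_ratio <- function(continuous_flow, flow_rate_ratio) {
  .check_positive(continuous_flow, "continuous_flow")
  .check_positive(flow_rate_ratio, "flow_rate_ratio")
  continuous_flow / flow_rate_ratio
}

#' Droplet volume of a sphere
#'
#' @param diameter Droplet diameter in micrometres.
#' @return Volume in microlitres.
#' @export
droplet_volume <- function(diameter) {
  .check_positive(diameter, "diameter")
  pi * diameter^3 / 6 * 1e-9
}

#' Generation rate by conservation of mass
#'
#' Assuming stable monodisperse generation, the dispersed flow is partitioned
#' into spheres of the observed diameter: `F = 6 * Q_d / (pi * D^3)`,
#' equivalently `Q_d = F * V_d`.
#'
#' @param dispersed_flow Dispersed-phase flow rate in uL/h.
#' @param diameter Droplet diameter in micrometres.
#' @return Generation rate in Hz.
#' @examples
#' generation_rate(1.885, 100) # ~1 Hz
#' @export
generation_rate <- function(dispersed_flow, diameter) {
  .check_positive(dispersed_flow, "dispersed_flow")
  .check_positive(diameter, "diameter")
  6 * dispersed_flow * .UL_H_TO_UM3_S / (pi * diameter^3)
}

#' Droplet diameter implied by a generation rate
#'
#' Inverse of [generation_rate()] at fixed dispersed flow.
#'
#' @inheritParams generation_rate
#' @param rate Generation rate in Hz.
#' @return Diameter in micrometres.
#' @export
diameter_from_rate <- function(dispersed_flow, rate) {
  .check_positive(dispersed_flow, "dispersed_flow")
  .check_positive(rate, "rate")
  (6 * dispersed_flow * .UL_H_TO_UM3_S / (pi * rate))^(1 / 3)
}

#' Continuous-to-dispersed viscosity ratio
#'
#' @param continuous_viscosity,dispersed_viscosity Dynamic viscosities, mPa.s.
#' @return Dimensionless ratio `lambda = mu_c / mu_d`.
#' @export
viscosity_ratio <- function(continuous_viscosity, dispersed_viscosity) {
  .check_positive(continuous_viscosity, "continuous_viscosity")
  .check_positive(dispersed_viscosity, "dispersed_viscosity")
  continuous_viscosity / dispersed_viscosity
}

#' Good-Girifalco interfacial tension approximation
#'
#' Approximates the interfacial tension between two immiscible liquids from
#' their individual surface tensions and molar volumes:
#' `sigma_cd = sigma_c + sigma_d - 2 * Phi_gg * sqrt(sigma_c * sigma_d)`,
#' with interaction coefficient
#' `Phi_gg = 4 * sqrt(V_c * V_d) / (sqrt(V_c) + sqrt(V_d))^2`, which equals 1
#' for equal molar volumes. `squared_denominator = FALSE` selects a legacy
#' variant with the unsquared denominator `sqrt(V_c) + sqrt(V_d)`; that form
#' is not dimensionless and is retained for compatibility only.
#'
#' A negative computed tension signals use outside the model's validity range
#' and raises an error rather than being clamped to zero.
#'
#' @param surface_tension_c,surface_tension_d Surface tensions of the
#'   continuous and dispersed fluids, mN/m.
#' @param molar_volume_c,molar_volume_d Molar volumes, cm^3/mol.
#' @param squared_denominator Use the dimensionless interaction coefficient
#'   (default) or the legacy unsquared form.
#' @return Interfacial tension in mN/m.
#' @examples
#' good_girifalco_ift(72, 18, 18, 18) # (sqrt(72) - sqrt(18))^2 = 18
#' @export
good_girifalco_ift <- function(surface_tension_c, surface_tension_d,
                               molar_volume_c, molar_volume_d,
                               squared_denominator = TRUE) {
  for (nm in c("surface_tension_c", "surface_tension_d",
               "molar_volume_c", "molar_volume_d")) {
    val <- get(nm)
    if (is.null(val) || anyNA(val)) {
      stop("insufficient fluid data: `", nm, "` is missing", call. = FALSE)
    }
    .check_positive(val, nm)
  }
  denom <- sqrt(molar_volume_c) + sqrt(molar_volume_d)
  if (isTRUE(squared_denominator)) denom <- denom^2
  phi_gg <- 4 * sqrt(molar_volume_c * molar_volume_d) / denom
  sigma <- surface_tension_c + surface_tension_d -
    2 * phi_gg * sqrt(surface_tension_c * surface_tension_d)
  if (any(sigma < -1e-12)) {
    stop("model out of validity range: computed interfacial tension is negative",
         call. = FALSE)
  }
  pmax(sigma, 0)
}

#' Fluid phase descriptor
#'
#' A one-row tibble describing a liquid phase: its dynamic viscosity and,
#' optionally, surface tension and molar volume (needed only for the
#' Good-Girifalco interfacial-tension approximation).
#'
#' @param name Label for the fluid.
#' @param viscosity Dynamic viscosity, mPa.s.
#' @param surface_tension Optional surface tension against air, mN/m.
#' @param molar_volume Optional molar volume, cm^3/mol.
#' @return A one-row tibble of class `fluid_phase`.
#' @examples
#' fluid_phase("DI water", 1.001, surface_tension = 72, molar_volume = 18)
#' @export
fluid_phase <- function(name, viscosity, surface_tension = NA_real_,
                        molar_volume = NA_real_) {
  .check_positive(viscosity, "viscosity")
  if (!is.na(surface_tension)) .check_positive(surface_tension, "surface_tension")
  if (!is.na(molar_volume)) .check_positive(molar_volume, "molar_volume")
  out <- tibble::tibble(
    name = as.character(name), viscosity = viscosity,
    surface_tension = surface_tension, molar_volume = molar_volume
  )
  class(out) <- c("fluid_phase", class(out))
  out
}

#' Flow-focusing junction geometry
#'
#' Raw channel dimensions of one flow-focusing junction, all in micrometres.
#' Normalized forms (each width or depth divided by the orifice width) and the
#' orifice hydraulic diameter are derived, not stored.
#'
#' @param orifice_width,channel_depth,dispersed_inlet_width,continuous_inlet_width,outlet_width
#'   Channel dimensions in micrometres; all must be positive.
#' @return A one-row tibble of class `flow_focuser` with the five raw
#'   dimensions plus derived `hydraulic_diameter_um` and normalized fields.
#' @examples
#' flow_focuser(22.5, 22.5, 22.5, 22.5, 22.5)
#' @export
flow_focuser <- function(orifice_width, channel_depth, dispersed_inlet_width,
                         continuous_inlet_width, outlet_width) {
  .check_positive(orifice_width, "orifice_width")
  .check_positive(channel_depth, "channel_depth")
  .check_positive(dispersed_inlet_width, "dispersed_inlet_width")
  .check_positive(continuous_inlet_width, "continuous_inlet_width")
  .check_positive(outlet_width, "outlet_width")
  out <- tibble::tibble(
    orifice_width_um = orifice_width,
    channel_depth_um = channel_depth,
    dispersed_inlet_width_um = dispersed_inlet_width,
    continuous_inlet_width_um = continuous_inlet_width,
    outlet_width_um = outlet_width,
    hydraulic_diameter_um = hydraulic_diameter(orifice_width, channel_depth),
    norm_channel_depth = channel_depth / orifice_width,
    norm_dispersed_inlet = dispersed_inlet_width / orifice_width,
    norm_continuous_inlet = continuous_inlet_width / orifice_width,
    norm_outlet = outlet_width / orifice_width
  )
  class(out) <- c("flow_focuser", class(out))
  out
}
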