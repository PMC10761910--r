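# Training-support envelope of the comprehensive droplet-generation dataset.

#' Parameter envelope of the comprehensive dataset
#'
#' Lower and upper bounds of every raw and derived quantity spanned by the
#' comprehensive single/double-emulsion dataset the predictive models are
#' meant to interpolate: output performance (diameter 15.5-245.1 um, rate
#' 5-11774 Hz, normalized diameter 0.35-1.60), fluid properties, geometry and
#' flow parameters. The envelope describes training support, not physical
#' validity: records outside it are loaded with a warning, never rejected.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @examples
#' droplet_envelope()
#' @export
droplet_envelope <- function() {
  tibble::tribble(
    ~parameter,               ~lower, ~upper,
    "diameter_um",              15.5,  245.1,
    "rate_hz",                     5,  11774,
    "norm_diameter",            0.35,   1.60,
    "dispersed_viscosity_mPas", 0.861,  3.431,
    "continuous_viscosity_mPas", 1.303, 57.2,
    "interfacial_tension_mNm", 0.318,  12.84,
    "viscosity_ratio",          0.47,   57.2,
    "orifice_width_um",           15,    175,
    "norm_channel_depth",          1,      3,
    "norm_continuous_inlet",       1,      4,
    "norm_dispersed_inlet",        1,      4,
    "norm_outlet",                 1,      6,
    "flow_rate_ratio",          0.69,     22,
    "capillary_number",        0.014,  9.399
  )
}

# scalar normalization constants for the design cost function: the envelope
# maxima of the two performance outputs
.DIAMETER_SCALE_UM <- 250
.RATE_SCALE_HZ <- 12000

#' Preset double-emulsion generator devices
#'
#' The six stock two-junction devices considered during double-emulsion design
#' automation: first-junction (FF1) orifice widths of 15, 22.5 and 30 um with a
#' normalized channel depth of either 1 or 1.33, the second junction (FF2)
#' twice as wide and deep as the first, and all inlet/outlet widths equal to
#' the local orifice width.
#'
#' @return A tibble with one row per device: `device_id`, FF1/FF2 orifice
#'   widths and the shared normalized depth.
#' @export
de_preset_devices <- function() {
  grid <- tidyr::expand_grid(
    orifice_ff1_um = c(15, 22.5, 30),
    norm_depth = c(1, 1.33)
  )
  dplyr::mutate(grid,
    device_id = sprintf("ff1_%g_h%g", .data$orifice_ff1_um, .data$norm_depth),
    orifice_ff2_um = 2 * .data$orifice_ff1_um,
    .before = 1
  )
}

# build the flow_focuser pair for one preset row (normalized widths all 1)
.preset_geometries <- function(preset) {
  w1 <- preset$orifice_ff1_um
  h1 <- w1 * preset$norm_depth
  w2 <- preset$orifice_ff2_um
  h2 <- w2 * preset$norm_depth
  list(
    ff1 = flow_focuser(w1, h1, w1, w1, w1),
    ff2 = flow_focuser(w2, h2, w2, w2, w2)
  )
}
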