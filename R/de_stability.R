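# Double-emulsion stability: couple two single-emulsion predictions at the
# FF1 and FF2 junctions and classify stability by the generation-rate
# difference (GRD). Stable single-core generation requires matched rates; if
# FF1 outruns FF2 some shells receive multiple cores, and if FF1 lags some
# shells receive none.

.DE_LABELS <- c("stable_single_core", "multiple_core", "missing_core")

#' Generation-rate difference between the two junctions
#'
#' Signed percentage mismatch `100 * (F1 - F2) / F1` between the
#' first-junction (core) and second-junction (shell) generation rates.
#'
#' @param f1,f2 Generation rates at FF1 and FF2, Hz.
#' @return Signed percentage.
#' @examples
#' grd(100, 85) # 15
#' grd(80, 100) # -25
#' @export
grd <- function(f1, f2) {
  .check_positive(f1, "f1")
  if (!is.numeric(f2) || any(!is.finite(f2))) {
    stop("`f2` must be a finite number", call. = FALSE)
  }
  100 * (f1 - f2) / f1
}

#' Classify double-emulsion stability from the GRD
#'
#' The stability band is strict: `|GRD| < threshold` is stable single-core;
#' boundary values are unstable. A positive excess (`GRD >= threshold`, FF1
#' faster) yields multiple cores; a negative excess yields missing cores.
#'
#' @param grd_pct Signed GRD percentages.
#' @param threshold Stability threshold in percent (default 15, the maximum
#'   GRD observed across experimentally stable double emulsions).
#' @return Factor with levels `stable_single_core`, `multiple_core`,
#'   `missing_core`.
#' @examples
#' classify_grd(c(10, 20, -20))
#' @export
classify_grd <- function(grd_pct, threshold = 15) {
  .check_positive(threshold, "threshold")
  out <- ifelse(abs(grd_pct) < threshold, "stable_single_core",
                ifelse(grd_pct >= threshold, "multiple_core", "missing_core"))
  factor(out, levels = .DE_LABELS)
}

#' Double-emulsion generator configuration
#'
#' Bundles the two junction geometries, the three fluids, the two interfacial
#' tensions and the three flow rates of one double-emulsion operating point.
#'
#' @param geometry_ff1,geometry_ff2 [flow_focuser()] geometries.
#' @param inner,middle,outer [fluid_phase()] descriptors.
#' @param ift_inner_middle,ift_middle_outer Interfacial tensions, mN/m.
#' @param q_inner,q_middle,q_outer Flow rates, uL/h.
#' @return A list of class `de_config`.
#' @export
de_config <- function(geometry_ff1, geometry_ff2, inner, middle, outer,
                      ift_inner_middle, ift_middle_outer,
                      q_inner, q_middle, q_outer) {
  stopifnot(inherits(geometry_ff1, "flow_focuser"),
            inherits(geometry_ff2, "flow_focuser"))
  .check_positive(ift_inner_middle, "ift_inner_middle")
  .check_positive(ift_middle_outer, "ift_middle_outer")
  .check_positive(q_inner, "q_inner")
  .check_positive(q_middle, "q_middle")
  .check_positive(q_outer, "q_outer")
  structure(list(
    geometry_ff1 = geometry_ff1, geometry_ff2 = geometry_ff2,
    inner = inner, middle = middle, outer = outer,
    ift_inner_middle = ift_inner_middle, ift_middle_outer = ift_middle_outer,
    q_inner = q_inner, q_middle = q_middle, q_outer = q_outer
  ), class = "de_config")
}

# Two model-input rows (FF1, FF2) for vectors of flow combinations under one
# configuration's geometry and fluids. Returns a list(ff1 =, ff2 =) of
# droplet datasets without outcome columns.
.de_records <- function(config, q_inner, q_middle, q_outer) {
  geom_row <- function(geom) {
    geom[c("orifice_width_um", "channel_depth_um", "dispersed_inlet_width_um",
           "continuous_inlet_width_um", "outlet_width_um")]
  }
  n <- length(q_inner)
  ff1 <- dplyr::bind_cols(
    tibble::tibble(emulsion_class = rep("DE_FF1", n)),
    geom_row(config$geometry_ff1)[rep(1, n), ],
    tibble::tibble(
      dispersed_viscosity_mPas = config$inner$viscosity,
      continuous_viscosity_mPas = config$middle$viscosity,
      interfacial_tension_mNm = config$ift_inner_middle,
      continuous_flow_ulh = q_middle,
      dispersed_flow_ulh = q_inner
    )
  )
  ff2 <- dplyr::bind_cols(
    tibble::tibble(emulsion_class = rep("DE_FF2", n)),
    geom_row(config$geometry_ff2)[rep(1, n), ],
    tibble::tibble(
      dispersed_viscosity_mPas = config$middle$viscosity,
      continuous_viscosity_mPas = config$outer$viscosity,
      interfacial_tension_mNm = config$ift_middle_outer,
      continuous_flow_ulh = q_outer,
      dispersed_flow_ulh = q_inner + q_middle
    )
  )
  list(ff1 = ff1, ff2 = ff2)
}

#' Predict double-emulsion generation from a configuration
#'
#' Runs the diameter model independently at each junction — inner fluid
#' dispersed into the middle at FF1, middle (at the combined inner + middle
#' flow, by conservation of mass) dispersed into the outer at FF2 — then
#' derives both generation rates, their GRD, and the stability label. A
#' predicted core at least as large as its shell raises a feasibility
#' warning flag (the rate arithmetic remains defined).
#'
#' @param config A [de_config()].
#' @param model A diameter model accepted by [predict_norm_diameter()].
#' @param threshold GRD stability threshold in percent.
#' @return A one-row tibble of class `de_prediction`: flows, inner/outer
#'   diameters (um), rates at both junctions (Hz), `grd_pct`, `label` and
#'   `feasibility_warning`.
#' @export
predict_de <- function(config, model, threshold = 15) {
  stopifnot(inherits(config, "de_config"))
  recs <- .de_records(config, config$q_inner, config$q_middle, config$q_outer)
  d_i <- predict_diameter(model, recs$ff1)
  d_o <- predict_diameter(model, recs$ff2)
  f1 <- generation_rate(config$q_inner, d_i)
  f2 <- generation_rate(config$q_inner + config$q_middle, d_o)
  g <- grd(f1, f2)
  out <- tibble::tibble(
    q_inner_ulh = config$q_inner, q_middle_ulh = config$q_middle,
    q_outer_ulh = config$q_outer,
    inner_diameter_um = d_i, outer_diameter_um = d_o,
    rate_ff1_hz = f1, rate_ff2_hz = f2,
    grd_pct = g, label = classify_grd(g, threshold),
    feasibility_warning = d_i >= d_o
  )
  class(out) <- c("de_prediction", class(out))
  out
}

#' Map double-emulsion stability over a flow grid
#'
#' Evaluates the coupled junction predictions over the full Cartesian grid of
#' inner, middle and outer flow rates and labels each point, identifying
#' likely stable and unstable operating regimes of a device.
#'
#' @param config A [de_config()] (its stored flows are ignored).
#' @param model A diameter model.
#' @param q_inner,q_middle,q_outer Positive flow-rate grids, uL/h.
#' @param threshold GRD stability threshold in percent.
#' @return A tibble of class `de_stability_map`, one row per grid point, with
#'   the same columns as [predict_de()].
#' @export
stability_map <- function(config, model, q_inner, q_middle, q_outer,
                          threshold = 15) {
  stopifnot(inherits(config, "de_config"))
  if (length(q_inner) == 0 || length(q_middle) == 0 || length(q_outer) == 0) {
    stop("empty flow grid", call. = FALSE)
  }
  .check_positive(q_inner, "q_inner")
  .check_positive(q_middle, "q_middle")
  .check_positive(q_outer, "q_outer")
  grid <- tidyr::expand_grid(q_inner_ulh = q_inner, q_middle_ulh = q_middle,
                             q_outer_ulh = q_outer)
  recs <- .de_records(config, grid$q_inner_ulh, grid$q_middle_ulh,
                      grid$q_outer_ulh)
  d_i <- predict_diameter(model, recs$ff1)
  d_o <- predict_diameter(model, recs$ff2)
  f1 <- generation_rate(grid$q_inner_ulh, d_i)
  f2 <- generation_rate(grid$q_inner_ulh + grid$q_middle_ulh, d_o)
  g <- grd(f1, f2)
  out <- dplyr::mutate(grid,
    inner_diameter_um = d_i, outer_diameter_um = d_o,
    rate_ff1_hz = f1, rate_ff2_hz = f2, grd_pct = g,
    label = classify_grd(g, threshold),
    feasibility_warning = d_i >= d_o
  )
  class(out) <- c("de_stability_map", class(out))
  out
}
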