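# Inverse design: turn a desired droplet diameter and/or generation rate into
# a device geometry and flow rates.
#
# Single emulsions: a dataset warm start (return the closest experimental
# point outright when it is within 3 um and 15 Hz of the request) followed by
# bounded coordinate descent over {orifice width, four normalized geometric
# parameters, capillary number, flow-rate ratio}, minimizing a scalar-
# normalized cost |Dtilde_desired - Dtilde| + |Ftilde_desired - Ftilde|.
# Double emulsions: exhaustive enumeration of the two junctions' flow space
# with conservation-of-mass pairing, a strict GRD stability filter, and
# ranking by percentage diameter error.

.DESIGN_PARAMS <- c("orifice_width_um", "norm_channel_depth",
                    "norm_dispersed_inlet", "norm_continuous_inlet",
                    "norm_outlet", "capillary_number", "flow_rate_ratio")

# envelope rows backing each search parameter
.PARAM_ENVELOPE_KEY <- c(
  orifice_width_um = "orifice_width_um",
  norm_channel_depth = "norm_channel_depth",
  norm_dispersed_inlet = "norm_dispersed_inlet",
  norm_continuous_inlet = "norm_continuous_inlet",
  norm_outlet = "norm_outlet",
  capillary_number = "capillary_number",
  flow_rate_ratio = "flow_rate_ratio"
)

#' Single-emulsion design request
#'
#' At least one of the desired diameter and rate must be given. Constraints
#' are named entries over the seven search parameters (`orifice_width_um`,
#' `norm_channel_depth`, `norm_dispersed_inlet`, `norm_continuous_inlet`,
#' `norm_outlet`, `capillary_number`, `flow_rate_ratio`): a single value fixes
#' the parameter, a length-2 vector `c(min, max)` bounds it (tightening or
#' deliberately widening the default training-envelope bounds).
#'
#' @param diameter Desired droplet diameter, um (optional if `rate` given).
#' @param rate Desired generation rate, Hz (optional if `diameter` given).
#' @param dispersed_viscosity,continuous_viscosity Fluid viscosities, mPa.s.
#' @param interfacial_tension Interfacial tension, mN/m.
#' @param constraints Named list of fixed values or `c(min, max)` bounds.
#' @return A list of class `design_request`.
#' @export
design_request <- function(diameter = NULL, rate = NULL,
                           dispersed_viscosity, continuous_viscosity,
                           interfacial_tension, constraints = list()) {
  if (is.null(diameter) && is.null(rate)) {
    stop("specify at least one of `diameter` and `rate`", call. = FALSE)
  }
  if (!is.null(diameter)) .check_positive(diameter, "diameter")
  if (!is.null(rate)) .check_positive(rate, "rate")
  .check_positive(dispersed_viscosity, "dispersed_viscosity")
  .check_positive(continuous_viscosity, "continuous_viscosity")
  .check_positive(interfacial_tension, "interfacial_tension")
  unknown <- setdiff(names(constraints), .DESIGN_PARAMS)
  if (length(unknown) > 0) {
    stop("unknown constraint parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    diameter = diameter, rate = rate,
    dispersed_viscosity = dispersed_viscosity,
    continuous_viscosity = continuous_viscosity,
    interfacial_tension = interfacial_tension,
    constraints = constraints
  ), class = "design_request")
}

# Resolve per-parameter [lower, upper] search bounds from the envelope and the
# request's constraints. Fixed constraints collapse to a zero-width interval.
.design_bounds <- function(request, envelope = droplet_envelope()) {
  env <- stats::setNames(
    lapply(.PARAM_ENVELOPE_KEY, function(k) {
      row <- envelope[envelope$parameter == k, ]
      c(row$lower, row$upper)
    }), names(.PARAM_ENVELOPE_KEY))
  for (nm in names(request$constraints)) {
    v <- request$constraints[[nm]]
    env[[nm]] <- if (length(v) == 1) c(v, v) else sort(as.numeric(v))
  }
  env
}

# Build model-input records from a matrix/data frame of search-parameter
# values plus the request's fluid properties.
.params_to_records <- function(params, request) {
  p <- tibble::as_tibble(params)
  w <- p$orifice_width_um
  h <- p$norm_channel_depth * w
  q_c <- continuous_flow_from_capillary(
    p$capillary_number, request$interfacial_tension, w, h,
    request$continuous_viscosity)
  tibble::tibble(
    emulsion_class = "SE",
    orifice_width_um = w,
    channel_depth_um = h,
    dispersed_inlet_width_um = p$norm_dispersed_inlet * w,
    continuous_inlet_width_um = p$norm_continuous_inlet * w,
    outlet_width_um = p$norm_outlet * w,
    dispersed_viscosity_mPas = request$dispersed_viscosity,
    continuous_viscosity_mPas = request$continuous_viscosity,
    interfacial_tension_mNm = request$interfacial_tension,
    continuous_flow_ulh = q_c,
    dispersed_flow_ulh = q_c / p$flow_rate_ratio
  )
}

#' Scalar-normalized design cost
#'
#' `C(x) = |Dtilde_desired - Dtilde_x| + |Ftilde_desired - Ftilde_x|`, where
#' diameters are normalized by 250 um and rates by 12000 Hz (the envelope
#' maxima of the two outputs) so that the much larger numeric range of rates
#' cannot dominate. Terms for unspecified targets are dropped. The cost is
#' zero exactly when the prediction matches the request in every requested
#' dimension.
#'
#' @param diameter,rate Predicted performance (um, Hz); vectors allowed.
#' @param request A [design_request()].
#' @return Dimensionless non-negative cost.
#' @export
design_cost <- function(diameter, rate, request) {
  cost <- 0
  if (!is.null(request$diameter)) {
    cost <- cost + abs(request$diameter - diameter) / .DIAMETER_SCALE_UM
  }
  if (!is.null(request$rate)) {
    cost <- cost + abs(request$rate - rate) / .RATE_SCALE_HZ
  }
  cost
}

.make_solution <- function(record, diameter, rate, cost, request, provenance,
                           converged = TRUE, iterations = 0L, trace = NULL,
                           n_evaluations = 0L) {
  geometry <- flow_focuser(record$orifice_width_um, record$channel_depth_um,
                           record$dispersed_inlet_width_um,
                           record$continuous_inlet_width_um,
                           record$outlet_width_um)
  structure(list(
    geometry = geometry,
    continuous_flow_ulh = record$continuous_flow_ulh,
    dispersed_flow_ulh = record$dispersed_flow_ulh,
    capillary_number = capillary_number(
      request$continuous_viscosity, request$interfacial_tension,
      record$continuous_flow_ulh, record$orifice_width_um,
      record$channel_depth_um),
    flow_rate_ratio = record$continuous_flow_ulh / record$dispersed_flow_ulh,
    predicted_diameter_um = diameter,
    predicted_rate_hz = rate,
    cost = cost,
    provenance = provenance,
    converged = converged,
    iterations = iterations,
    n_evaluations = n_evaluations,
    trace = trace,
    request = request
  ), class = "design_solution")
}

#' @export
print.design_solution <- function(x, ...) {
  cat("Single-emulsion design (", x$provenance, ")\n", sep = "")
  g <- x$geometry
  cat(sprintf("  orifice %.3g um, depth %.3g um, inlets %.3g/%.3g um, outlet %.3g um\n",
              g$orifice_width_um, g$channel_depth_um,
              g$dispersed_inlet_width_um, g$continuous_inlet_width_um,
              g$outlet_width_um))
  cat(sprintf("  Qc %.4g uL/h, Qd %.4g uL/h (Ca %.4g, flow ratio %.4g)\n",
              x$continuous_flow_ulh, x$dispersed_flow_ulh,
              x$capillary_number, x$flow_rate_ratio))
  cat(sprintf("  predicted: %.3g um at %.4g Hz; cost %.3g (%s after %d iterations)\n",
              x$predicted_diameter_um, x$predicted_rate_hz, x$cost,
              if (x$converged) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Closest admissible experimental point for a design request
#'
#' Finds the dataset record closest to the request under scalar-normalized
#' Euclidean distance in (diameter, rate), restricted to records satisfying
#' the request's constraints. The record is returned as a solution only if it
#' matches the request within 3 um and 15 Hz (checked for the specified
#' targets only); otherwise `NULL`.
#'
#' @param request A [design_request()].
#' @param data A droplet dataset of experimental records.
#' @param max_diameter_gap,max_rate_gap Admissibility margins, um and Hz.
#' @return A `design_solution` with provenance `"experimental_point"`, or
#'   `NULL`.
#' @export
nearest_experimental_point <- function(request, data,
                                       max_diameter_gap = 3,
                                       max_rate_gap = 15) {
  idx <- .nearest_admissible_index(request, data)
  if (is.null(idx)) return(NULL)
  rec <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])[idx, ]
  ok <- TRUE
  if (!is.null(request$diameter)) {
    ok <- ok && abs(rec$diameter_um - request$diameter) < max_diameter_gap
  }
  if (!is.null(request$rate)) {
    ok <- ok && abs(rec$rate_hz - request$rate) < max_rate_gap
  }
  if (!ok) return(NULL)
  .make_solution(rec, rec$diameter_um, rec$rate_hz,
                 design_cost(rec$diameter_um, rec$rate_hz, request),
                 request, "experimental_point")
}

# index of the closest admissible record, or NULL if none admissible
.nearest_admissible_index <- function(request, data) {
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  ok <- rep(TRUE, nrow(d))
  for (nm in names(request$constraints)) {
    v <- request$constraints[[nm]]
    x <- d[[nm]]
    ok <- ok & if (length(v) == 1) {
      abs(x - v) <= 1e-9 * pmax(abs(v), 1)
    } else {
      x >= min(v) & x <= max(v)
    }
  }
  if (!any(ok)) return(NULL)
  dist2 <- rep(0, nrow(d))
  if (!is.null(request$diameter)) {
    dist2 <- dist2 + ((d$diameter_um - request$diameter) / .DIAMETER_SCALE_UM)^2
  }
  if (!is.null(request$rate)) {
    dist2 <- dist2 + ((d$rate_hz - request$rate) / .RATE_SCALE_HZ)^2
  }
  dist2[!ok] <- Inf
  which.min(dist2)
}

#' Automated single-emulsion design
#'
#' Searches geometry and dimensionless flow inputs for a design whose
#' predicted diameter and/or rate matches the request. If a dataset is
#' supplied, the closest admissible experimental point is used as warm start
#' and returned outright when it already matches within 3 um and 15 Hz.
#' Otherwise bounded coordinate descent runs for at most `max_iter`
#' iterations: every free parameter is stepped up and down by
#' `step_fraction` of its admissible range, the single best cost-reducing
#' move is accepted, and the search stops when the cost reaches zero, the
#' improvement falls below `tol`, or the budget is exhausted (in which case
#' the best design found is returned with `converged = FALSE`).
#'
#' @param request A [design_request()].
#' @param model A diameter model accepted by [predict_norm_diameter()]
#'   (typically the consensus model).
#' @param data Optional droplet dataset for the experimental warm start.
#' @param max_iter Iteration budget.
#' @param tol Convergence tolerance on the cost improvement.
#' @param step_fraction Step size as a fraction of each parameter's range.
#' @param envelope Envelope providing default parameter bounds and the
#'   achievable diameter/rate support used for the feasibility check.
#' @return A `design_solution`.
#' @export
design_se <- function(request, model, data = NULL, max_iter = 5000,
                      tol = 1e-9, step_fraction = 0.01,
                      envelope = droplet_envelope()) {
  stopifnot(inherits(request, "design_request"))
  support_d <- unlist(envelope[envelope$parameter == "diameter_um",
                               c("lower", "upper")])
  support_f <- unlist(envelope[envelope$parameter == "rate_hz",
                               c("lower", "upper")])
  if (!is.null(request$diameter) &&
      (request$diameter < support_d[1] || request$diameter > support_d[2])) {
    stop(sprintf("infeasible request: diameter %g um outside supported range [%g, %g] um",
                 request$diameter, support_d[1], support_d[2]), call. = FALSE)
  }
  if (!is.null(request$rate) &&
      (request$rate < support_f[1] || request$rate > support_f[2])) {
    stop(sprintf("infeasible request: rate %g Hz outside supported range [%g, %g] Hz",
                 request$rate, support_f[1], support_f[2]), call. = FALSE)
  }
  bounds <- .design_bounds(request, envelope)
  if (any(vapply(bounds, function(b) b[1] > b[2], TRUE))) {
    stop("infeasible request: empty bound interval in constraints", call. = FALSE)
  }

  if (!is.null(data)) {
    shortcut <- nearest_experimental_point(request, data)
    if (!is.null(shortcut)) return(shortcut)
  }

  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  steps <- step_fraction * (upper - lower)
  free <- steps > 0

  # starting point: closest admissible experimental record if available,
  # otherwise the midpoint of the bounds
  x <- (lower + upper) / 2
  if (!is.null(data)) {
    idx <- .nearest_admissible_index(request, data)
    if (!is.null(idx)) {
      d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])[idx, ]
      x <- pmin(pmax(unlist(d[.DESIGN_PARAMS]), lower), upper)
    }
  }
  names(x) <- .DESIGN_PARAMS

  eval_points <- function(mat) {
    recs <- .params_to_records(mat, request)
    diam <- predict_diameter(model, recs)
    rate <- generation_rate(recs$dispersed_flow_ulh, diam)
    list(records = recs, diameter = diam, rate = rate,
         cost = design_cost(diam, rate, request))
  }

  cur <- eval_points(t(x))
  cost <- cur$cost
  n_eval <- 1L
  trace <- numeric(max_iter + 1L)
  trace[1] <- cost
  iterations <- 0L
  converged <- FALSE

  if (!any(free)) {
    sol <- .make_solution(cur$records, cur$diameter, cur$rate, cost, request,
                          "search", converged = TRUE, iterations = 0L,
                          n_evaluations = n_eval,
                          trace = tibble::tibble(iteration = 0L, cost = cost))
    return(sol)
  }

  for (it in seq_len(max_iter)) {
    cand <- list()
    for (j in which(free)) {
      for (sgn in c(-1, 1)) {
        xj <- x
        xj[j] <- min(max(x[j] + sgn * steps[j], lower[j]), upper[j])
        if (xj[j] != x[j]) cand[[length(cand) + 1L]] <- xj
      }
    }
    if (length(cand) == 0) { converged <- TRUE; break }
    mat <- do.call(rbind, cand)
    ev <- eval_points(mat)
    n_eval <- n_eval + nrow(mat)
    best <- which.min(ev$cost)
    iterations <- it
    if (ev$cost[best] < cost) {
      improvement <- cost - ev$cost[best]
      x <- cand[[best]]
      cost <- ev$cost[best]
      cur <- lapply(ev, function(v) if (is.data.frame(v)) v[best, ] else v[best])
      trace[it + 1L] <- cost
      if (cost == 0 || improvement < tol) { converged <- TRUE; break }
    } else {
      # no cost-reducing move at this step size: local optimum
      trace[it + 1L] <- cost
      converged <- TRUE
      break
    }
  }

  trace_tbl <- tibble::tibble(iteration = 0:iterations,
                              cost = trace[seq_len(iterations + 1L)])
  .make_solution(cur$records, cur$diameter, cur$rate, cost, request, "search",
                 converged = converged || cost == 0, iterations = iterations,
                 n_evaluations = n_eval, trace = trace_tbl)
}

#' Performance heat map around a designed operating point
#'
#' Predicted diameters and generation rates for continuous and dispersed flow
#' rates up to `span` (default 25%) either side of the designed values, as a
#' device-specific operating guideline. The center cell reproduces the
#' solution's own prediction.
#'
#' @param solution A `design_solution`.
#' @param model The diameter model used for the design.
#' @param span Half-width of the flow sweep as a fraction of the design value.
#' @param n Grid points per axis (odd values keep the design at the center).
#' @return A tibble of class `performance_heatmap` with the two flows, the
#'   predictions and an `is_center` flag.
#' @export
performance_heatmap <- function(solution, model, span = 0.25, n = 5) {
  stopifnot(inherits(solution, "design_solution"))
  factors <- seq(1 - span, 1 + span, length.out = n)
  grid <- tidyr::expand_grid(
    q_c_ulh = solution$continuous_flow_ulh * factors,
    q_d_ulh = solution$dispersed_flow_ulh * factors
  )
  g <- solution$geometry
  req <- solution$request
  recs <- tibble::tibble(
    emulsion_class = "SE",
    orifice_width_um = g$orifice_width_um,
    channel_depth_um = g$channel_depth_um,
    dispersed_inlet_width_um = g$dispersed_inlet_width_um,
    continuous_inlet_width_um = g$continuous_inlet_width_um,
    outlet_width_um = g$outlet_width_um,
    dispersed_viscosity_mPas = req$dispersed_viscosity,
    continuous_viscosity_mPas = req$continuous_viscosity,
    interfacial_tension_mNm = req$interfacial_tension,
    continuous_flow_ulh = grid$q_c_ulh,
    dispersed_flow_ulh = grid$q_d_ulh
  )
  diam <- predict_diameter(model, recs)
  out <- dplyr::mutate(grid,
    diameter_um = diam,
    rate_hz = generation_rate(grid$q_d_ulh, diam),
    is_center = abs(.data$q_c_ulh - solution$continuous_flow_ulh) <
      1e-9 * solution$continuous_flow_ulh &
      abs(.data$q_d_ulh - solution$dispersed_flow_ulh) <
      1e-9 * solution$dispersed_flow_ulh
  )
  class(out) <- c("performance_heatmap", class(out))
  out
}

#' Double-emulsion design request
#'
#' @param inner_diameter,outer_diameter Desired core and shell diameters, um.
#' @param inner,middle,outer [fluid_phase()] descriptors of the three fluids.
#' @param ift_inner_middle,ift_middle_outer Interfacial tensions, mN/m.
#' @return A list of class `de_design_request`.
#' @export
de_design_request <- function(inner_diameter, outer_diameter,
                              inner, middle, outer,
                              ift_inner_middle, ift_middle_outer) {
  .check_positive(inner_diameter, "inner_diameter")
  .check_positive(outer_diameter, "outer_diameter")
  .check_positive(ift_inner_middle, "ift_inner_middle")
  .check_positive(ift_middle_outer, "ift_middle_outer")
  structure(list(
    inner_diameter = inner_diameter, outer_diameter = outer_diameter,
    inner = inner, middle = middle, outer = outer,
    ift_inner_middle = ift_inner_middle, ift_middle_outer = ift_middle_outer
  ), class = "de_design_request")
}

#' Automated double-emulsion design
#'
#' Enumerates the flow space of the two junctions (defaults: inner 50-650
#' uL/h, middle 200-1200 uL/h, outer 1500-10000 uL/h) for each candidate
#' device, pairing every second-junction point with the matching combined
#' inner + middle flow so the final design upholds conservation of mass.
#' Combinations with a predicted absolute GRD of 5% or more are deemed
#' unstable and excluded; the survivors are ranked by the mean percentage
#' error of the predicted inner and outer diameters from the requested
#' values, with ties broken by smaller |GRD|, then smaller total flow, then
#' lexicographic flows. If no combination passes the GRD filter an explicit
#' empty result is returned (`found = FALSE`), not an error.
#'
#' @param request A [de_design_request()].
#' @param model A diameter model (typically the consensus model).
#' @param devices Either a preset table as from [de_preset_devices()] (all six
#'   presets are tried by default), or a custom `list(ff1 =, ff2 =)` pair of
#'   [flow_focuser()] geometries.
#' @param q_inner,q_middle,q_outer Flow grids, uL/h.
#' @param grd_threshold Stability threshold for the design filter, percent.
#' @param n_top Number of ranked alternatives to retain.
#' @return A list of class `de_design`: `found`, `best` (one-row tibble or
#'   `NULL`), `solutions` (ranked tibble), `n_evaluated`, `request`.
#' @export
design_de <- function(request, model, devices = de_preset_devices(),
                      q_inner = seq(50, 650, by = 25),
                      q_middle = seq(200, 1200, by = 50),
                      q_outer = seq(1500, 10000, by = 250),
                      grd_threshold = 5, n_top = 100L) {
  stopifnot(inherits(request, "de_design_request"))
  .check_positive(grd_threshold, "grd_threshold")
  device_list <- if (is.data.frame(devices)) {
    lapply(seq_len(nrow(devices)), function(i) {
      c(list(device_id = devices$device_id[i]),
        .preset_geometries(devices[i, ]))
    })
  } else {
    stopifnot(inherits(devices$ff1, "flow_focuser"),
              inherits(devices$ff2, "flow_focuser"))
    list(list(device_id = "custom", ff1 = devices$ff1, ff2 = devices$ff2))
  }

  n_evaluated <- 0L
  all_rows <- purrr::map(device_list, function(dev) {
    config <- de_config(dev$ff1, dev$ff2, request$inner, request$middle,
                        request$outer, request$ift_inner_middle,
                        request$ift_middle_outer,
                        q_inner[1], q_middle[1], q_outer[1])
    # FF1 depends only on (q_i, q_m); FF2 only on (q_i + q_m, q_o)
    ff1_grid <- tidyr::expand_grid(q_inner_ulh = q_inner,
                                   q_middle_ulh = q_middle)
    recs1 <- .de_records(config, ff1_grid$q_inner_ulh, ff1_grid$q_middle_ulh,
                         rep(q_outer[1], nrow(ff1_grid)))$ff1
    ff1_grid$inner_diameter_um <- predict_diameter(model, recs1)
    ff1_grid$rate_ff1_hz <- generation_rate(ff1_grid$q_inner_ulh,
                                            ff1_grid$inner_diameter_um)
    ff1_grid$q_total_ulh <- ff1_grid$q_inner_ulh + ff1_grid$q_middle_ulh

    ff2_grid <- tidyr::expand_grid(
      q_total_ulh = sort(unique(ff1_grid$q_total_ulh)),
      q_outer_ulh = q_outer)
    recs2 <- .de_records(config, ff2_grid$q_total_ulh * 0, # placeholder
                         ff2_grid$q_total_ulh, ff2_grid$q_outer_ulh)
    # .de_records sums inner+middle for FF2; pass the total via q_middle
    recs2 <- recs2$ff2
    ff2_grid$outer_diameter_um <- predict_diameter(model, recs2)
    ff2_grid$rate_ff2_hz <- generation_rate(ff2_grid$q_total_ulh,
                                            ff2_grid$outer_diameter_um)

    rows <- dplyr::inner_join(ff1_grid, ff2_grid, by = "q_total_ulh",
                              relationship = "many-to-many")
    n_evaluated <<- n_evaluated + nrow(rows)
    rows$grd_pct <- grd(rows$rate_ff1_hz, rows$rate_ff2_hz)
    rows <- dplyr::filter(rows, abs(.data$grd_pct) < grd_threshold)
    if (nrow(rows) == 0) return(rows)
    rows$error_pct <- 100 * (
      abs(rows$inner_diameter_um - request$inner_diameter) / request$inner_diameter +
      abs(rows$outer_diameter_um - request$outer_diameter) / request$outer_diameter) / 2
    rows$device_id <- dev$device_id
    rows
  })
  solutions <- dplyr::bind_rows(all_rows)
  if (nrow(solutions) > 0) {
    solutions <- dplyr::arrange(solutions, .data$error_pct, abs(.data$grd_pct),
                                .data$q_total_ulh + .data$q_outer_ulh,
                                .data$q_inner_ulh, .data$q_middle_ulh,
                                .data$q_outer_ulh)
    solutions <- dplyr::select(solutions, "device_id", "q_inner_ulh",
                               "q_middle_ulh", "q_outer_ulh", "q_total_ulh",
                               "inner_diameter_um", "outer_diameter_um",
                               "rate_ff1_hz", "rate_ff2_hz", "grd_pct",
                               "error_pct")
    solutions <- utils::head(solutions, n_top)
  }
  structure(list(
    found = nrow(solutions) > 0,
    best = if (nrow(solutions) > 0) solutions[1, ] else NULL,
    solutions = solutions,
    n_evaluated = n_evaluated,
    grd_threshold = grd_threshold,
    request = request
  ), class = "de_design")
}

#' @export
print.de_design <- function(x, ...) {
  if (!x$found) {
    cat("Double-emulsion design: no solution (no flow combination with |GRD| <",
        x$grd_threshold, "% found)\n")
    return(invisible(x))
  }
  b <- x$best
  cat("Double-emulsion design: best of", nrow(x$solutions),
      "stable candidates (", x$n_evaluated, "evaluated )\n")
  cat(sprintf("  device %s: Qi %g, Qm %g, Qo %g uL/h\n", b$device_id,
              b$q_inner_ulh, b$q_middle_ulh, b$q_outer_ulh))
  cat(sprintf("  predicted inner %.3g um / outer %.3g um (GRD %.2f%%, error %.2f%%)\n",
              b$inner_diameter_um, b$outer_diameter_um, b$grd_pct, b$error_pct))
  invisible(x)
}
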