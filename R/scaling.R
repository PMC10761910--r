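# Empirical scaling laws for the normalized droplet diameter.
#
# Two functional forms are supported, both fit by ordinary least squares in
# log space:
#   literature_power_law:      Dbar = a * Phi^b * Ca^c * lambda^d
#   proposed_interaction_law:  Dbar = a * Phi^(b + c*ln(Ca)) * Ca^d * lambda^e
# The interaction form lets the effect of the flow-rate ratio vary from low to
# high capillary numbers.

.SCALING_FORMS <- c("literature_power_law", "proposed_interaction_law")

#' Fit a scaling law for normalized droplet diameter
#'
#' Least-squares fit in log space of the normalized diameter against the
#' dimensionless flow inputs (flow-rate ratio, capillary number, viscosity
#' ratio). The coefficient vector is named `a` (prefactor) followed by the
#' exponents in the order of the chosen form.
#'
#' @param data A droplet dataset (diameter column required).
#' @param form_id `"literature_power_law"` for the independent power law, or
#'   `"proposed_interaction_law"` for the form with a flow-ratio-by-capillary
#'   interaction exponent.
#' @return An object of class `scaling_law` with elements `form_id`,
#'   `coefficients`, `training_mape`, `n` and the underlying `lm` fit.
#' @examples
#' d <- generate_droplets(synthetic_config(n_records = 200, seed = 1))
#' fit_scaling_law(d, "literature_power_law")
#' @export
fit_scaling_law <- function(data, form_id = c("literature_power_law",
                                              "proposed_interaction_law")) {
  form_id <- match.arg(form_id)
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  if (nrow(d) < 10) stop("need at least 10 records to fit a scaling law",
                         call. = FALSE)
  if (any(d$norm_diameter <= 0)) {
    stop("all normalized diameters must be positive", call. = FALSE)
  }
  df <- data.frame(
    ld = log(d$norm_diameter),
    lphi = log(d$flow_rate_ratio),
    lca = log(d$capillary_number),
    llam = log(d$viscosity_ratio)
  )
  fml <- if (form_id == "literature_power_law") {
    ld ~ lphi + lca + llam
  } else {
    ld ~ lphi + lphi:lca + lca + llam
  }
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    stop("unidentifiable coefficients: design matrix is rank-deficient ",
         "(a dimensionless input may be constant)", call. = FALSE)
  }
  cf <- stats::coef(fit)
  coefficients <- if (form_id == "literature_power_law") {
    c(a = unname(exp(cf["(Intercept)"])), b = unname(cf["lphi"]),
      c = unname(cf["lca"]), d = unname(cf["llam"]))
  } else {
    c(a = unname(exp(cf["(Intercept)"])), b = unname(cf["lphi"]),
      c = unname(cf["lphi:lca"]), d = unname(cf["lca"]),
      e = unname(cf["llam"]))
  }
  obj <- structure(
    list(form_id = form_id, coefficients = coefficients, fit = fit,
         n = nrow(d)),
    class = "scaling_law"
  )
  pred_um <- predict_norm_diameter(obj, d) * d$hydraulic_diameter_um
  obj$training_mape <- evaluate(pred_um, d$diameter_um)$mape
  obj
}

#' @export
print.scaling_law <- function(x, ...) {
  cat("Scaling law (", x$form_id, "), fit to ", x$n, " records\n", sep = "")
  print(round(x$coefficients, 5))
  cat("training diameter MAPE:", sprintf("%.2f%%", x$training_mape), "\n")
  invisible(x)
}

# Evaluate a scaling-law functional form at given dimensionless inputs.
.scaling_law_value <- function(form_id, cf, phi, ca, lambda) {
  switch(form_id,
    literature_power_law =
      cf["a"] * phi^cf["b"] * ca^cf["c"] * lambda^cf["d"],
    proposed_interaction_law =
      cf["a"] * phi^(cf["b"] + cf["c"] * log(ca)) * ca^cf["d"] * lambda^cf["e"],
    stop("unknown scaling-law form: ", form_id, call. = FALSE)
  )
}
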