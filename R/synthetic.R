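# Synthetic droplet-generation benchmark with known ground truth.
#
# Records are sampled log-uniformly over the training-support envelope, the
# normalized diameter is produced by a configurable power law, and the
# generation rate follows by conservation of mass from the (noisy) diameter.
# Rows are rejection-sampled so that every emitted record lies inside the
# envelope and passes dataset validation with zero warnings. Double-emulsion
# experiments are emitted as FF1/FF2 row pairs whose outer flow is solved so
# the noise-free generation-rate difference falls in a configurable band.

#' Ground-truth scaling law for synthetic data
#'
#' `Dbar = a * Phi^b * Ca^c * lambda^d * Hbar^e`, with multiplicative
#' lognormal observation noise on the diameter. The default coefficients are
#' monotone decreasing in capillary number and flow-rate ratio with a weak
#' viscosity-ratio effect, keeping normalized diameters near the observed
#' 0.35-1.60 band; they are test fixtures, not claims about physics.
#'
#' @param a,b,c,d,e Prefactor and exponents on flow-rate ratio, capillary
#'   number, viscosity ratio and normalized depth.
#' @param noise_sd Relative standard deviation of the multiplicative
#'   lognormal diameter noise.
#' @return A list of class `truth_law`.
#' @export
truth_law <- function(a = 1.0, b = -0.10, c = -0.25, d = 0.05, e = 0.0,
                      noise_sd = 0.02) {
  stopifnot(a > 0, noise_sd >= 0)
  structure(list(a = a, b = b, c = c, d = d, e = e, noise_sd = noise_sd),
            class = "truth_law")
}

#' Evaluate a ground-truth law (noise-free)
#'
#' @param law A [truth_law()].
#' @param flow_rate_ratio,ca,lambda,norm_depth Dimensionless inputs.
#' @return Noise-free normalized diameters.
#' @export
law_norm_diameter <- function(law, flow_rate_ratio, ca, lambda, norm_depth = 1) {
  stopifnot(inherits(law, "truth_law"))
  law$a * flow_rate_ratio^law$b * ca^law$c * lambda^law$d * norm_depth^law$e
}

#' Synthetic dataset configuration
#'
#' @param n_records Number of rows in the emitted dataset (a double-emulsion
#'   experiment contributes two rows).
#' @param de_fraction Fraction of rows emitted as double-emulsion FF1/FF2
#'   pairs; `2 * round(de_fraction * n_records / 2)` rows become pairs.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param envelope Sampling and validation envelope.
#' @param grd_band Band (percent) from which each synthetic pair's noise-free
#'   generation-rate difference is drawn.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_records = 868L, de_fraction = 0, seed = 0L,
                             envelope = droplet_envelope(),
                             grd_band = c(-5, 5)) {
  stopifnot(n_records >= 1, de_fraction >= 0, de_fraction <= 1,
            length(grd_band) == 2)
  if (any(envelope$lower >= envelope$upper) || any(envelope$lower <= 0)) {
    stop("infeasible envelope bounds", call. = FALSE)
  }
  structure(list(
    n_records = as.integer(n_records), de_fraction = de_fraction,
    seed = as.integer(seed), envelope = envelope,
    grd_band = sort(as.numeric(grd_band))
  ), class = "synthetic_config")
}

.env_bound <- function(envelope, parameter) {
  row <- envelope[envelope$parameter == parameter, ]
  c(row$lower, row$upper)
}

.runif_log <- function(n, bound) exp(stats::runif(n, log(bound[1]), log(bound[2])))

# draw one batch of candidate SE rows (noise applied); no envelope filter yet
.sample_se_batch <- function(m, law, env) {
  w <- .runif_log(m, .env_bound(env, "orifice_width_um"))
  hbar <- .runif_log(m, .env_bound(env, "norm_channel_depth"))
  diw <- .runif_log(m, .env_bound(env, "norm_dispersed_inlet"))
  ciw <- .runif_log(m, .env_bound(env, "norm_continuous_inlet"))
  ocw <- .runif_log(m, .env_bound(env, "norm_outlet"))
  ca <- .runif_log(m, .env_bound(env, "capillary_number"))
  phi <- .runif_log(m, .env_bound(env, "flow_rate_ratio"))
  mu_d <- .runif_log(m, .env_bound(env, "dispersed_viscosity_mPas"))
  mu_c <- .runif_log(m, .env_bound(env, "continuous_viscosity_mPas"))
  sigma <- .runif_log(m, .env_bound(env, "interfacial_tension_mNm"))
  h <- hbar * w
  q_c <- continuous_flow_from_capillary(ca, sigma, w, h, mu_c)
  q_d <- q_c / phi
  dbar <- law_norm_diameter(law, phi, ca, mu_c / mu_d, hbar)
  noise <- if (law$noise_sd > 0) exp(stats::rnorm(m, 0, law$noise_sd)) else 1
  diam <- dbar * hydraulic_diameter(w, h) * noise
  tibble::tibble(
    emulsion_class = "SE",
    orifice_width_um = w, channel_depth_um = h,
    dispersed_inlet_width_um = diw * w,
    continuous_inlet_width_um = ciw * w,
    outlet_width_um = ocw * w,
    dispersed_viscosity_mPas = mu_d, continuous_viscosity_mPas = mu_c,
    interfacial_tension_mNm = sigma,
    continuous_flow_ulh = q_c, dispersed_flow_ulh = q_d,
    diameter_um = diam, rate_hz = generation_rate(q_d, diam)
  )
}

# TRUE for rows whose raw and derived fields all fall inside the envelope
.in_envelope <- function(rows, env) {
  d <- derive_features(rows)
  ok <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(env))) {
    col <- env$parameter[i]
    if (!col %in% names(d)) next
    ok <- ok & d[[col]] >= env$lower[i] & d[[col]] <= env$upper[i]
  }
  ok
}

# sample one DE experiment pair; returns a 2-row dataset or NULL if no outer
# flow in range realizes a GRD inside the band
.sample_de_pair <- function(law, env, grd_band, id) {
  w1 <- stats::runif(1, 15, 30)
  h1 <- w1
  geom1 <- flow_focuser(w1, h1, w1, w1, w1)
  geom2 <- flow_focuser(2 * w1, 2 * h1, 2 * w1, 2 * w1, 2 * w1)
  mu_i <- .runif_log(1, .env_bound(env, "dispersed_viscosity_mPas"))
  mu_m <- .runif_log(1, .env_bound(env, "continuous_viscosity_mPas"))
  mu_o <- .runif_log(1, .env_bound(env, "continuous_viscosity_mPas"))
  ift_im <- .runif_log(1, .env_bound(env, "interfacial_tension_mNm"))
  ift_mo <- .runif_log(1, .env_bound(env, "interfacial_tension_mNm"))
  q_i <- .runif_log(1, c(50, 650))
  q_m <- .runif_log(1, c(200, 1200))
  q_tot <- q_i + q_m

  phi1 <- q_m / q_i
  ca1 <- capillary_number(mu_m, ift_im, q_m, w1, h1)
  d_i <- law_norm_diameter(law, phi1, ca1, mu_m / mu_i, h1 / w1) *
    geom1$hydraulic_diameter_um
  f1 <- generation_rate(q_i, d_i)

  target_grd <- stats::runif(1, grd_band[1], grd_band[2])
  grd_at <- function(q_o) {
    phi2 <- q_o / q_tot
    ca2 <- capillary_number(mu_o, ift_mo, q_o,
                            geom2$orifice_width_um, geom2$channel_depth_um)
    d_o <- law_norm_diameter(law, phi2, ca2, mu_o / mu_m, 1) *
      geom2$hydraulic_diameter_um
    grd(f1, generation_rate(q_tot, d_o)) - target_grd
  }
  q_lo <- max(1500, 0.69 * q_tot)
  q_hi <- min(10000, 22 * q_tot)
  if (q_lo >= q_hi) return(NULL)
  g_lo <- grd_at(q_lo); g_hi <- grd_at(q_hi)
  if (!is.finite(g_lo) || !is.finite(g_hi) || g_lo * g_hi > 0) return(NULL)
  q_o <- stats::uniroot(grd_at, c(q_lo, q_hi), tol = 1e-8)$root

  phi2 <- q_o / q_tot
  ca2 <- capillary_number(mu_o, ift_mo, q_o,
                          geom2$orifice_width_um, geom2$channel_depth_um)
  d_o <- law_norm_diameter(law, phi2, ca2, mu_o / mu_m, 1) *
    geom2$hydraulic_diameter_um
  noise <- if (law$noise_sd > 0) exp(stats::rnorm(2, 0, law$noise_sd)) else c(1, 1)
  expand_de_experiment(
    inner = fluid_phase("inner", mu_i), middle = fluid_phase("middle", mu_m),
    outer = fluid_phase("outer", mu_o),
    geometry_ff1 = geom1, geometry_ff2 = geom2,
    ift_inner_middle = ift_im, ift_middle_outer = ift_mo,
    q_inner = q_i, q_middle = q_m, q_outer = q_o,
    inner_diameter = d_i * noise[1], outer_diameter = d_o * noise[2],
    record_id = id, source_tag = "synthetic"
  )
}

#' Generate a synthetic droplet dataset with known ground truth
#'
#' Samples device geometries, fluid properties and flow conditions
#' log-uniformly over the envelope, produces diameters from the ground-truth
#' law with multiplicative lognormal noise, and derives rates by conservation
#' of mass. Single-emulsion rows are rejection-sampled until all raw and
#' derived fields fall inside the envelope, so the emitted dataset passes
#' validation with zero warnings under default bounds. Double-emulsion pairs
#' share the FF1/FF2 structure of the experimental devices (FF2 twice the
#' FF1 orifice) with the outer flow solved so the noise-free rate mismatch
#' lies in `grd_band`.
#'
#' @param config A [synthetic_config()].
#' @param law A [truth_law()].
#' @return A droplet dataset tibble of `config$n_records` rows with
#'   `record_id` and `source_tag` columns and all derived fields.
#' @examples
#' d <- generate_droplets(synthetic_config(n_records = 100, seed = 1))
#' @export
generate_droplets <- function(config = synthetic_config(), law = truth_law()) {
  stopifnot(inherits(config, "synthetic_config"), inherits(law, "truth_law"))
  env <- config$envelope
  n_de_pairs <- round(config$de_fraction * config$n_records / 2)
  n_se <- config$n_records - 2L * n_de_pairs
  withr::with_seed(config$seed, {
    se_rows <- list()
    n_have <- 0L
    guard <- 0L
    while (n_have < n_se) {
      guard <- guard + 1L
      if (guard > 1000L) stop("rejection sampling failed to fill the envelope",
                              call. = FALSE)
      batch <- .sample_se_batch(max(2L * (n_se - n_have), 64L), law, env)
      batch <- batch[.in_envelope(batch, env), , drop = FALSE]
      if (nrow(batch) > 0) {
        se_rows[[length(se_rows) + 1L]] <- batch
        n_have <- n_have + nrow(batch)
      }
    }
    se <- utils::head(dplyr::bind_rows(se_rows), n_se)
    if (n_se > 0) se$record_id <- sprintf("se_%05d", seq_len(n_se))
    if (n_se > 0) se$source_tag <- "synthetic"

    de <- list()
    guard <- 0L
    while (length(de) < n_de_pairs) {
      guard <- guard + 1L
      if (guard > 100L * max(n_de_pairs, 1L)) {
        stop("rejection sampling failed for double-emulsion pairs", call. = FALSE)
      }
      pair <- .sample_de_pair(law, env, config$grd_band,
                              sprintf("de_%05d", length(de) + 1L))
      if (!is.null(pair)) de[[length(de) + 1L]] <- pair
    }
    out <- dplyr::bind_rows(se, dplyr::bind_rows(de))
  })
  derive_features(out[setdiff(names(out), .DERIVED_COLUMNS)])
}

#' Coefficient-recovery report for a fitted scaling law
#'
#' Compares a fitted literature-form scaling law against the ground-truth law
#' that generated the data. The truth must have no normalized-depth effect
#' (`e = 0`), matching the fitted functional form.
#'
#' @param law The generating [truth_law()].
#' @param fitted A `scaling_law` fit of form `literature_power_law`.
#' @return A tibble with `coefficient`, `true`, `fitted`, `abs_error`.
#' @export
recovery_report <- function(law, fitted) {
  stopifnot(inherits(law, "truth_law"), inherits(fitted, "scaling_law"))
  if (fitted$form_id != "literature_power_law" || law$e != 0) {
    stop("form mismatch: recovery requires a literature_power_law fit and a ",
         "truth law with no depth effect (e = 0)", call. = FALSE)
  }
  truth <- c(a = law$a, b = law$b, c = law$c, d = law$d)
  est <- fitted$coefficients[names(truth)]
  tibble::tibble(
    coefficient = names(truth),
    true = unname(truth),
    fitted = unname(est),
    abs_error = abs(unname(truth) - unname(est))
  )
}
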