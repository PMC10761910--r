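# Reading, validation, featurization and splitting of droplet-generation
# datasets.
#
# A droplet dataset is an ordinary tibble with one row per droplet-generation
# experiment (double-emulsion experiments contribute two rows, one per
# junction). Raw columns carry explicit units in their names; dimensionless
# derived columns are always recomputed from the raw ones.

.REQUIRED_COLUMNS <- c(
  "emulsion_class",
  "orifice_width_um", "channel_depth_um", "dispersed_inlet_width_um",
  "continuous_inlet_width_um", "outlet_width_um",
  "dispersed_viscosity_mPas", "continuous_viscosity_mPas",
  "interfacial_tension_mNm",
  "continuous_flow_ulh", "dispersed_flow_ulh",
  "diameter_um", "rate_hz"
)

.DERIVED_COLUMNS <- c(
  "hydraulic_diameter_um", "norm_diameter", "capillary_number",
  "flow_rate_ratio", "viscosity_ratio", "norm_channel_depth",
  "norm_dispersed_inlet", "norm_continuous_inlet", "norm_outlet"
)

.EMULSION_CLASSES <- c("SE", "DE_FF1", "DE_FF2")

#' Recompute derived dimensionless fields of a droplet dataset
#'
#' Adds (or overwrites) the hydraulic diameter, normalized diameter, capillary
#' number, flow-rate ratio, viscosity ratio and normalized geometric fields,
#' all computed from the raw unit-bearing columns.
#'
#' @param data A droplet dataset (tibble with the raw schema columns).
#' @return The input with the derived columns appended.
#' @export
derive_features <- function(data) {
  missing <- setdiff(setdiff(.REQUIRED_COLUMNS, c("diameter_um", "rate_hz")),
                     names(data))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(data,
    hydraulic_diameter_um = hydraulic_diameter(.data$orifice_width_um,
                                               .data$channel_depth_um),
    capillary_number = capillary_number(.data$continuous_viscosity_mPas,
                                        .data$interfacial_tension_mNm,
                                        .data$continuous_flow_ulh,
                                        .data$orifice_width_um,
                                        .data$channel_depth_um),
    flow_rate_ratio = .data$continuous_flow_ulh / .data$dispersed_flow_ulh,
    viscosity_ratio = viscosity_ratio(.data$continuous_viscosity_mPas,
                                      .data$dispersed_viscosity_mPas),
    norm_channel_depth = .data$channel_depth_um / .data$orifice_width_um,
    norm_dispersed_inlet = .data$dispersed_inlet_width_um / .data$orifice_width_um,
    norm_continuous_inlet = .data$continuous_inlet_width_um / .data$orifice_width_um,
    norm_outlet = .data$outlet_width_um / .data$orifice_width_um
  )
  if ("diameter_um" %in% names(out)) {
    out <- dplyr::mutate(out,
      norm_diameter = .data$diameter_um / .data$hydraulic_diameter_um)
  }
  out
}

#' Validate a droplet dataset against the training envelope
#'
#' Recomputes every derived field from the raw columns, compares against any
#' stored derived values (relative disagreement above `derived_tol` is
#' warned about), and flags values outside the training-support envelope.
#'
#' @param data A droplet dataset.
#' @param envelope Envelope bounds as returned by [droplet_envelope()].
#' @param derived_tol Relative tolerance before a stored derived value is
#'   considered inconsistent with the raw fields.
#' @return A load report: list with `n_records`, `n_out_of_envelope`,
#'   `n_derived_mismatch` and a `warnings` character vector.
#' @export
validate_droplets <- function(data, envelope = droplet_envelope(),
                              derived_tol = 0.01) {
  warnings <- character()
  stored <- data[intersect(.DERIVED_COLUMNS, names(data))]
  fresh <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  n_mismatch <- 0L
  for (col in names(stored)) {
    rel <- abs(stored[[col]] - fresh[[col]]) / abs(fresh[[col]])
    bad <- which(is.finite(rel) & rel > derived_tol)
    if (length(bad) > 0) {
      n_mismatch <- n_mismatch + length(bad)
      warnings <- c(warnings, sprintf(
        "stored `%s` disagrees with value recomputed from raw fields by >%g%% in %d row(s) (first: row %d)",
        col, derived_tol * 100, length(bad), bad[1]))
    }
  }
  n_out <- 0L
  env <- envelope
  for (i in seq_len(nrow(env))) {
    col <- env$parameter[i]
    if (!col %in% names(fresh)) next
    x <- fresh[[col]]
    bad <- which(is.finite(x) & (x < env$lower[i] | x > env$upper[i]))
    if (length(bad) > 0) {
      n_out <- n_out + length(bad)
      warnings <- c(warnings, sprintf(
        "`%s` outside training envelope [%g, %g] in %d row(s) (first: row %d)",
        col, env$lower[i], env$upper[i], length(bad), bad[1]))
    }
  }
  list(n_records = nrow(data), n_out_of_envelope = n_out,
       n_derived_mismatch = n_mismatch, warnings = warnings)
}

#' Read a droplet dataset from CSV
#'
#' Reads a comma-separated, UTF-8 dataset with one header row and the required
#' unit-suffixed columns, recomputes all derived dimensionless fields from the
#' raw ones, and cross-checks/envelope-audits the result. Out-of-envelope
#' records and stored-derived-value mismatches produce warnings, never
#' rejection. The load report is attached as attribute `"load_report"`.
#'
#' @param path Path to a CSV file.
#' @param envelope Envelope bounds used for the audit.
#' @return A droplet dataset tibble with derived columns.
#' @export
read_droplets <- function(path, envelope = droplet_envelope()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # parse all cells as text, then convert through strtod: exact double
  # round-trip and precise error locations for malformed cells
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(.REQUIRED_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(raw), c("emulsion_class", "record_id", "source_tag"))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(num) & !is.na(raw[[col]]))
    if (length(bad) > 0 && col %in% .REQUIRED_COLUMNS) {
      stop(sprintf("non-numeric value in column `%s` (data line %d)",
                   col, bad[1] + 1L), call. = FALSE)
    }
    if (length(bad) == 0) raw[[col]] <- num
  }
  bad_class <- !raw$emulsion_class %in% .EMULSION_CLASSES
  if (any(bad_class)) {
    stop("unknown emulsion_class (expected SE, DE_FF1 or DE_FF2) at data line ",
         which(bad_class)[1] + 1L, call. = FALSE)
  }
  report <- validate_droplets(raw, envelope = envelope)
  for (w in report$warnings) warning(w, call. = FALSE)
  out <- derive_features(raw[setdiff(names(raw), .DERIVED_COLUMNS)])
  attr(out, "load_report") <- report
  out
}

#' Write a droplet dataset to CSV
#'
#' Writes raw and derived columns with full round-trip numeric precision.
#'
#' @param data A droplet dataset.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_droplets <- function(data, path) {
  # 17 significant digits guarantee an exact double round trip
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Expand a double-emulsion experiment into two single-emulsion records
#'
#' A double-emulsion experiment is modeled as two independent droplet
#' generation events: at the first junction (FF1) the inner fluid is dispersed
#' into the middle fluid; at the second junction (FF2) the middle fluid
#' (carrying the cores) is dispersed into the outer fluid. Conservation of
#' mass fixes the FF2 dispersed flow to the sum of the inner and middle flows.
#' Diameters are normalized by each junction's own hydraulic diameter, and
#' generation rates are computed from the observed diameters and the dispersed
#' flows by conservation of mass.
#'
#' @param inner,middle,outer [fluid_phase()] descriptors of the three fluids.
#' @param geometry_ff1,geometry_ff2 [flow_focuser()] geometries of the two
#'   junctions.
#' @param ift_inner_middle,ift_middle_outer Interfacial tensions at the two
#'   interfaces, mN/m.
#' @param q_inner,q_middle,q_outer Flow rates of the three fluids, uL/h.
#' @param inner_diameter,outer_diameter Observed core and shell diameters, um.
#' @param record_id Optional id stem; the two rows get suffixes `_ff1`/`_ff2`.
#' @param source_tag Provenance label.
#' @return A two-row droplet dataset (`emulsion_class` `DE_FF1`, `DE_FF2`).
#' @export
expand_de_experiment <- function(inner, middle, outer,
                                 geometry_ff1, geometry_ff2,
                                 ift_inner_middle, ift_middle_outer,
                                 q_inner, q_middle, q_outer,
                                 inner_diameter, outer_diameter,
                                 record_id = "de", source_tag = "expanded") {
  .check_positive(q_inner, "q_inner")
  .check_positive(q_middle, "q_middle")
  .check_positive(q_outer, "q_outer")
  .check_positive(inner_diameter, "inner_diameter")
  .check_positive(outer_diameter, "outer_diameter")
  row <- function(class, geom, mu_d, mu_c, ift, q_d, q_c, diam, suffix) {
    tibble::tibble(
      record_id = paste0(record_id, suffix),
      emulsion_class = class,
      orifice_width_um = geom$orifice_width_um,
      channel_depth_um = geom$channel_depth_um,
      dispersed_inlet_width_um = geom$dispersed_inlet_width_um,
      continuous_inlet_width_um = geom$continuous_inlet_width_um,
      outlet_width_um = geom$outlet_width_um,
      dispersed_viscosity_mPas = mu_d,
      continuous_viscosity_mPas = mu_c,
      interfacial_tension_mNm = ift,
      continuous_flow_ulh = q_c,
      dispersed_flow_ulh = q_d,
      diameter_um = diam,
      rate_hz = generation_rate(q_d, diam),
      source_tag = source_tag
    )
  }
  out <- dplyr::bind_rows(
    row("DE_FF1", geometry_ff1, inner$viscosity, middle$viscosity,
        ift_inner_middle, q_inner, q_middle, inner_diameter, "_ff1"),
    row("DE_FF2", geometry_ff2, middle$viscosity, outer$viscosity,
        ift_middle_outer, q_inner + q_middle, q_outer, outer_diameter, "_ff2")
  )
  derive_features(out)
}

#' Dimensionless feature table for the diameter models
#'
#' Returns the model design matrix as a tibble with columns in the fixed
#' order: orifice width, (viscosity ratio, if included), capillary number,
#' flow-rate ratio, then the four normalized geometric parameters. The
#' regression target of all diameter models is the normalized diameter.
#'
#' @param data A droplet dataset.
#' @param include_viscosity_ratio The boosted-tree featurization keeps the
#'   viscosity ratio (8 features); the neural network drops it (7 features).
#' @return A tibble of features, one row per record.
#' @export
featurize <- function(data, include_viscosity_ratio = TRUE) {
  d <- derive_features(data[setdiff(names(data), .DERIVED_COLUMNS)])
  cols <- c("orifice_width_um",
            if (include_viscosity_ratio) "viscosity_ratio",
            "capillary_number", "flow_rate_ratio",
            "norm_channel_depth", "norm_dispersed_inlet",
            "norm_continuous_inlet", "norm_outlet")
  d[cols]
}

#' Randomized train/test session splits
#'
#' Splits a dataset into disjoint, exhaustive train/test pairs, once per seed
#' (default 15 sessions, seeds 0-14). The test set holds
#' `floor(test_fraction * n)` records; splits are simple random and
#' reproducible per seed.
#'
#' @param data A droplet dataset.
#' @param test_fraction Proportion held out for testing.
#' @param seeds Integer seeds, one per session; must be distinct.
#' @return A list of sessions, each `list(seed =, train =, test =)`.
#' @export
split_sessions <- function(data, test_fraction = 0.2, seeds = 0:14) {
  n <- nrow(data)
  if (n < 5) stop("dataset too small to split (need at least 5 records)",
                  call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(seeds)) stop("`seeds` must be distinct", call. = FALSE)
  n_test <- floor(test_fraction * n)
  lapply(seeds, function(s) {
    idx <- withr::with_seed(s, sample.int(n, n_test))
    list(seed = s, train = data[-idx, , drop = FALSE],
         test = data[idx, , drop = FALSE])
  })
}
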