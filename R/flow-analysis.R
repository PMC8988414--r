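# Local flow at stenosis measurement sites by the three routes: the solved
# Windkessel network (I_W), the invasive FFR reading (I_I), and the benchtop
# distal pressure reading (I_B). The invasive and benchtop routes share one
# formula: flow = (aortic pressure - distal pressure) / path impedance, with
# the path impedance taken as the series sum of the per-segment RC impedance
# magnitudes along the ostium-to-site chain -- exactly the series rule the
# network itself obeys, so a noiseless measurement reproduces the model flow.

solution_element <- function(solution, segment_id) {
  i <- match(paste0("seg_", segment_id), solution$elements$element_id)
  if (is.na(i)) lookup_error(sprintf("no element for segment '%s' in solution", segment_id))
  i
}

check_solution <- function(solution) {
  if (!inherits(solution, "flow_solution")) {
    state_error("need a solved network (`flow_solution`); run nodal_solve()/simulate_flow() first")
  }
  invisible(solution)
}

#' Windkessel flow at a measurement site
#'
#' The solved flow through the site segment's element: the model's prediction
#' of the flow crossing the stenosis measurement location.
#'
#' @param solution a `flow_solution` from [nodal_solve()]/[simulate_flow()].
#' @param tree the `coronary_tree` the network was built from.
#' @param site segment id of a measurement site.
#' @return Flow in cc/s.
#' @export
windkessel_site_flow <- function(solution, tree, site) {
  check_solution(solution)
  i_seg <- segment_row(tree, site)
  if (!tree$segments$is_measurement_site[i_seg]) {
    lookup_error(sprintf("segment '%s' is not a measurement site", site))
  }
  solution$elements$flow_cc_s[solution_element(solution, site)]
}

#' Model-predicted distal/aortic pressure ratio at a site
#'
#' The pressure at the site segment's downstream node divided by the source
#' pressure: the model analogue of fractional flow reserve, in (0, 1] for
#' passive networks.
#'
#' @param solution a `flow_solution`.
#' @param site segment id of a measurement site.
#' @return Dimensionless ratio.
#' @export
model_ffr <- function(solution, site) {
  check_solution(solution)
  solution$elements$downstream_pressure_dyn_cm2[solution_element(solution, site)] /
    solution$source_pressure
}

#' Series impedance of the ostium-to-site path
#'
#' Sum of the per-segment impedance magnitudes (Poiseuille resistance with
#' the segment's material compliance at the cardiac fundamental) along
#' [path_to_site()]. Under `compliance_mode = "per_artery"` the segments are
#' pure resistors and this is the summed Poiseuille resistance.
#'
#' @param tree a `coronary_tree`.
#' @param params a [hemo_params()].
#' @param site segment id of a measurement site.
#' @return Impedance in dyn.s/cm5.
#' @export
path_impedance <- function(tree, params, site) {
  stopifnot(inherits(params, "hemo_params"))
  path <- path_to_site(tree, site)
  R_i <- poiseuille_resistance(params$viscosity_poise, path$length_cm, path$mean_radius_cm)
  C_i <- if (params$compliance_mode == "per_segment") {
    segment_compliance(params$material_area_compliance_mm2_mmHg, path$length_cm)
  } else {
    rep(0, nrow(path))
  }
  sum(impedance(R_i, C_i, params$cardiac_period_s))
}

#' Invasive-FFR-derived flow at a site
#'
#' Converts an invasive fractional flow reserve reading to a local flow:
#' distal pressure `P_d = ffr * P_a`, flow `(P_a - P_d) / Z_path` with
#' `Z_path` from [path_impedance()]. Readings above 1 (wire drift/noise) are
#' clamped to 1 with a warning; an FFR of exactly 1 means no gradient and
#' zero flow.
#'
#' @param ffr invasive FFR in (0, 1.2].
#' @param params a [hemo_params()].
#' @param tree a `coronary_tree`.
#' @param site segment id of a measurement site.
#' @return Flow in cc/s.
#' @export
invasive_site_flow <- function(ffr, params, tree, site) {
  if (!is.numeric(ffr) || length(ffr) != 1L || !is.finite(ffr) ||
      ffr <= 0 || ffr > 1.2) {
    value_error("ffr must be a single value in (0, 1.2]")
  }
  if (ffr > 1) {
    warn_coroflow(sprintf("FFR %.3f > 1 clamped to 1 (zero gradient)", ffr),
                  "coroflow_clamp_warning")
    ffr <- 1
  }
  P_a <- params$mean_aortic_pressure_dyn_cm2
  max(P_a - ffr * P_a, 0) / path_impedance(tree, params, site)
}

#' Benchtop-pressure-derived flow at a site
#'
#' Same formula as [invasive_site_flow()] with the distal pressure taken
#' directly from the benchtop sensor reading (in mmHg) instead of
#' `ffr * P_a`; `benchtop_site_flow(ffr * P_a)` and `invasive_site_flow(ffr)`
#' coincide exactly.
#'
#' @param distal_pressure_mmHg sensor pressure at the site, mmHg; must be
#'   positive and not exceed the aortic pressure.
#' @param params a [hemo_params()].
#' @param tree a `coronary_tree`.
#' @param site segment id of a measurement site.
#' @return Flow in cc/s.
#' @export
benchtop_site_flow <- function(distal_pressure_mmHg, params, tree, site) {
  if (!is.numeric(distal_pressure_mmHg) || length(distal_pressure_mmHg) != 1L ||
      !is.finite(distal_pressure_mmHg) || distal_pressure_mmHg <= 0) {
    value_error("distal pressure must be a single positive value")
  }
  P_a <- params$mean_aortic_pressure_dyn_cm2
  P_d <- convert_pressure(distal_pressure_mmHg, "mmHg", "dyn_cm2")
  if (P_d > P_a) value_error("distal pressure exceeds aortic pressure")
  (P_a - P_d) / path_impedance(tree, params, site)
}

#' Sweep activity states and report site flows by all three methods
#'
#' Rebuilds, recalibrates and solves the network for every activity state and
#' reports, per site and state, the Windkessel flow and model pressure ratio,
#' plus (when measurements are supplied) the invasive- and benchtop-derived
#' flows. Per-state coronary inflow / aortic outflow totals are attached as
#' attribute `"totals"`.
#'
#' @param tree a `coronary_tree`.
#' @param params a [hemo_params()].
#' @param chamber a [chamber_params()].
#' @param states list of [activity_state()]s (default
#'   [default_activity_states()]).
#' @param sites measurement-site segment ids; default all sites in the tree.
#' @param measurements optional data frame with columns `segment_id`,
#'   `activity`, `invasive_ffr`, `benchtop_distal_pressure_mmHg`
#'   (see [read_measurements()]); `NA` cells yield `NA` flows.
#' @return Data frame of class `site_flow_report` with columns `site`,
#'   `artery`, `activity`, `I_invasive_cc_s`, `I_benchtop_cc_s`,
#'   `I_windkessel_cc_s`, `model_ffr`, `significant` (model ratio <= 0.8),
#'   and attribute `"totals"`.
#' @export
activity_sweep <- function(tree, params, chamber,
                           states = default_activity_states(),
                           sites = NULL, measurements = NULL) {
  stopifnot(inherits(tree, "coronary_tree"))
  sites <- sites %||% measurement_sites(tree)
  rows <- list()
  totals <- list()
  for (state in states) {
    sim <- simulate_flow(tree, params, state, chamber)
    sol <- sim$solution
    totals[[length(totals) + 1L]] <- data.frame(
      activity = state$name,
      coronary_inflow_cc_s = coronary_inflow(sol),
      aortic_outflow_cc_s = outlet_flow(sol),
      total_cc_s = source_flow(sol),
      stringsAsFactors = FALSE
    )
    for (s in sites) {
      ffr_m <- model_ffr(sol, s)
      I_I <- I_B <- NA_real_
      if (!is.null(measurements)) {
        m <- measurements[measurements$segment_id == s &
                            measurements$activity == state$name, , drop = FALSE]
        if (nrow(m) > 1L) {
          value_error(sprintf("multiple measurements for site %s at state %s", s, state$name))
        }
        if (nrow(m) == 1L) {
          if (!is.na(m$invasive_ffr)) {
            I_I <- invasive_site_flow(m$invasive_ffr, params, tree, s)
          }
          if (!is.na(m$benchtop_distal_pressure_mmHg)) {
            I_B <- benchtop_site_flow(m$benchtop_distal_pressure_mmHg, params, tree, s)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = s,
        artery = tree$segments$artery[segment_row(tree, s)],
        activity = state$name,
        I_invasive_cc_s = I_I,
        I_benchtop_cc_s = I_B,
        I_windkessel_cc_s = windkessel_site_flow(sol, tree, s),
        model_ffr = ffr_m,
        significant = ffr_m <= 0.8,
        stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    site = character(), artery = character(), activity = character(),
    I_invasive_cc_s = numeric(), I_benchtop_cc_s = numeric(),
    I_windkessel_cc_s = numeric(), model_ffr = numeric(),
    significant = logical(), stringsAsFactors = FALSE
  )
  attr(report, "totals") <- do.call(rbind, totals)
  class(report) <- c("site_flow_report", class(report))
  report
}

#' Read site measurements from CSV
#'
#' Dialect: header `segment_id,activity,invasive_ffr,benchtop_distal_pressure_mmHg`,
#' empty cell = missing; each row must carry at least one of the two readings.
#'
#' @param path input CSV path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  cols <- c("segment_id", "activity", "invasive_ffr", "benchtop_distal_pressure_mmHg")
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!identical(header, paste(cols, collapse = ","))) {
    format_error("CSV header does not match the measurement dialect")
  }
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  out <- data.frame(
    segment_id = raw$segment_id,
    activity = raw$activity,
    invasive_ffr = parse_strict_numeric(raw$invasive_ffr, "invasive_ffr",
                                        allow_empty = TRUE),
    benchtop_distal_pressure_mmHg = parse_strict_numeric(
      raw$benchtop_distal_pressure_mmHg, "benchtop_distal_pressure_mmHg",
      allow_empty = TRUE),
    stringsAsFactors = FALSE
  )
  if (!all(out$activity %in% ACTIVITY_LEVELS)) {
    format_error("activity must be one of R, E1, E2")
  }
  if (any(is.na(out$invasive_ffr) & is.na(out$benchtop_distal_pressure_mmHg))) {
    value_error("each measurement row needs at least one reading")
  }
  out
}

#' Write site measurements to CSV
#' @param measurements data frame as returned by [read_measurements()] or
#'   [generate_measurements()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  rows <- paste(
    measurements$segment_id, measurements$activity,
    fmt_full(measurements$invasive_ffr),
    fmt_full(measurements$benchtop_distal_pressure_mmHg),
    sep = ","
  )
  writeLines(c("segment_id,activity,invasive_ffr,benchtop_distal_pressure_mmHg", rows),
             path, useBytes = TRUE)
  invisible(path)
}

#' Write a site-flow report to CSV
#'
#' Columns: `site,activity,I_invasive_cc_s,I_benchtop_cc_s,I_windkessel_cc_s,model_ffr`.
#'
#' @param report a `site_flow_report` from [activity_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  rows <- paste(
    report$site, report$activity,
    fmt_full(report$I_invasive_cc_s), fmt_full(report$I_benchtop_cc_s),
    fmt_full(report$I_windkessel_cc_s), fmt_full(report$model_ffr),
    sep = ","
  )
  writeLines(c("site,activity,I_invasive_cc_s,I_benchtop_cc_s,I_windkessel_cc_s,model_ffr",
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a site-flow report written by [write_report_csv()]
#' @param path input path.
#' @return Data frame with the report columns.
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  cols <- c("site", "activity", "I_invasive_cc_s", "I_benchtop_cc_s",
            "I_windkessel_cc_s", "model_ffr")
  header <- readLines(path, n = 1L, warn = FALSE)
  if (!identical(header, paste(cols, collapse = ","))) {
    format_error("CSV header does not match the site-flow report dialect")
  }
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  data.frame(
    site = raw$site,
    activity = raw$activity,
    I_invasive_cc_s = parse_strict_numeric(raw$I_invasive_cc_s, "I_invasive_cc_s", TRUE),
    I_benchtop_cc_s = parse_strict_numeric(raw$I_benchtop_cc_s, "I_benchtop_cc_s", TRUE),
    I_windkessel_cc_s = parse_strict_numeric(raw$I_windkessel_cc_s, "I_windkessel_cc_s", TRUE),
    model_ffr = parse_strict_numeric(raw$model_ffr, "model_ffr", TRUE),
    stringsAsFactors = FALSE
  )
}
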