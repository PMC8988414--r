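# Element-level physics of the electrical analogy, in CGS hydraulic units:
# pressure dyn/cm2 (voltage), flow cm3/s (current), resistance dyn*s/cm5,
# volume compliance cm5/dyn = cm3 per (dyn/cm2) (capacitance).

#' Unit conversion constant: 1 mmHg in dyn/cm2
#' @format A length-one numeric.
#' @export
MMHG_TO_DYN_CM2 <- 1333.22

ARTERY_LABELS <- c("LAD", "LCX", "RCA")
ACTIVITY_LEVELS <- c("R", "E1", "E2")

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    value_error(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

#' Global hemodynamic parameters
#'
#' Bundles the scalar constants of the model: working-fluid viscosity, mean
#' aortic (source) pressure, cardiac period, the target total input flow the
#' aortic outlet is calibrated against, and the printed-material area
#' compliance applied to the vessel wall.
#'
#' Defaults: blood-mimicking fluid at 3.7 cP (0.037 poise), 100 mmHg source
#' pressure, 0.8 s cardiac period (75 bpm), 8.33 cc/s total input flow, and
#' 0.0975 mm^2/mmHg area compliance (midpoint of the healthy-vessel range
#' 0.075-0.120 replicated by soft photopolymer prints).
#'
#' @param viscosity_poise dynamic viscosity mu in poise.
#' @param mean_aortic_pressure_dyn_cm2 source pressure in dyn/cm2.
#' @param cardiac_period_s cardiac cycle length Tc in seconds.
#' @param total_input_flow_cc_s calibration target for total source flow, cc/s.
#' @param material_area_compliance_mm2_mmHg wall area compliance, mm^2/mmHg.
#' @param compliance_mode `"per_segment"` places each segment's material
#'   compliance in its own RC element; `"per_artery"` treats segments as pure
#'   resistors and lumps the artery's summed compliance at its chamber.
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(viscosity_poise = 0.037,
                        mean_aortic_pressure_dyn_cm2 = 100 * MMHG_TO_DYN_CM2,
                        cardiac_period_s = 0.8,
                        total_input_flow_cc_s = 8.33,
                        material_area_compliance_mm2_mmHg = 0.0975,
                        compliance_mode = c("per_segment", "per_artery")) {
  check_positive_scalar(viscosity_poise, "viscosity_poise")
  check_positive_scalar(mean_aortic_pressure_dyn_cm2, "mean_aortic_pressure_dyn_cm2")
  check_positive_scalar(cardiac_period_s, "cardiac_period_s")
  check_positive_scalar(total_input_flow_cc_s, "total_input_flow_cc_s")
  check_positive_scalar(material_area_compliance_mm2_mmHg, "material_area_compliance_mm2_mmHg")
  structure(
    list(
      viscosity_poise = viscosity_poise,
      mean_aortic_pressure_dyn_cm2 = mean_aortic_pressure_dyn_cm2,
      cardiac_period_s = cardiac_period_s,
      total_input_flow_cc_s = total_input_flow_cc_s,
      material_area_compliance_mm2_mmHg = material_area_compliance_mm2_mmHg,
      compliance_mode = match.arg(compliance_mode)
    ),
    class = "hemo_params"
  )
}

#' Activity-state distal boundary resistance
#'
#' One physical-activity state of the distal (arteriolar/capillary-bed)
#' boundary: a resistance per main coronary artery, constrained to the
#' physically realisable catheter range 50,000-300,000 dyn.s/cm5.
#'
#' @param name one of `"R"` (rest), `"E1"` (light exercise), `"E2"` (moderate
#'   exercise).
#' @param distal_resistance_dyn_s_cm5 named numeric vector over (a subset of)
#'   LAD/LCX/RCA.
#' @return An object of class `activity_state`.
#' @export
activity_state <- function(name, distal_resistance_dyn_s_cm5) {
  if (!is.character(name) || length(name) != 1L || !name %in% ACTIVITY_LEVELS) {
    value_error("activity `name` must be one of 'R', 'E1', 'E2'")
  }
  r <- distal_resistance_dyn_s_cm5
  if (is.null(names(r)) || !all(names(r) %in% ARTERY_LABELS)) {
    value_error("distal resistances must be named with artery labels LAD/LCX/RCA")
  }
  if (!all(is.finite(r)) || any(r < 50000) || any(r > 300000)) {
    value_error("distal resistances must lie in [50000, 300000] dyn.s/cm5")
  }
  structure(
    list(name = name, distal_resistance_dyn_s_cm5 = r),
    class = "activity_state"
  )
}

#' Default activity states
#'
#' Rest and two exercise levels with per-artery distal resistances
#' R = 250,000, E1 = 120,000, E2 = 60,000 dyn.s/cm5 (monotone with activity,
#' inside the realisable 50,000-300,000 range).
#'
#' @return Named list of three `activity_state` objects, ordered R, E1, E2.
#' @export
default_activity_states <- function() {
  per <- function(x) stats::setNames(rep(x, 3L), ARTERY_LABELS)
  states <- list(
    R  = activity_state("R",  per(250000)),
    E1 = activity_state("E1", per(120000)),
    E2 = activity_state("E2", per(60000))
  )
  validate_activity_states(states)
  states
}

# resistance must fall strictly with activity, per artery
validate_activity_states <- function(states) {
  byname <- stats::setNames(states, vapply(states, `[[`, "", "name"))
  if (all(c("R", "E1", "E2") %in% names(byname))) {
    for (a in names(byname$R$distal_resistance_dyn_s_cm5)) {
      rr <- byname$R$distal_resistance_dyn_s_cm5[[a]]
      r1 <- byname$E1$distal_resistance_dyn_s_cm5[[a]]
      r2 <- byname$E2$distal_resistance_dyn_s_cm5[[a]]
      if (!(rr > r1 && r1 > r2)) {
        value_error(sprintf("distal resistance must satisfy R > E1 > E2 for artery %s", a))
      }
    }
  }
  invisible(states)
}

#' Compliance-chamber boundary parameters
#'
#' The three-chamber distal collection boundary: each main artery drains into
#' a chamber with an inherent viscous resistance (LAD/LCX/RCA = 1671/1820/591
#' dyn.s/cm5) in parallel with a trapped-gas compliance derived from Boyle's
#' law at the chamber's initial pressure/volume and the systolic/diastolic
#' working pressures.
#'
#' @param inherent_resistance_dyn_s_cm5 named vector of chamber resistances.
#' @param P0_mmHg initial (atmospheric) chamber pressure, mmHg.
#' @param V0_mm3 initial trapped-gas volume, mm^3.
#' @param Ps_mmHg,Pd_mmHg systolic and diastolic chamber pressures, mmHg
#'   (`Ps_mmHg > Pd_mmHg > 0`).
#' @return An object of class `chamber_params`.
#' @export
chamber_params <- function(inherent_resistance_dyn_s_cm5 =
                             c(LAD = 1671, LCX = 1820, RCA = 591),
                           P0_mmHg = 760,
                           V0_mm3 = 4.4e4,
                           Ps_mmHg = 120,
                           Pd_mmHg = 80) {
  r <- inherent_resistance_dyn_s_cm5
  if (is.null(names(r)) || !all(names(r) %in% ARTERY_LABELS) || any(r <= 0)) {
    value_error("chamber resistances must be positive and named LAD/LCX/RCA")
  }
  check_positive_scalar(P0_mmHg, "P0_mmHg")
  check_positive_scalar(V0_mm3, "V0_mm3")
  check_positive_scalar(Ps_mmHg, "Ps_mmHg")
  check_positive_scalar(Pd_mmHg, "Pd_mmHg")
  if (Ps_mmHg <= Pd_mmHg) value_error("Ps_mmHg must exceed Pd_mmHg")
  structure(
    list(
      inherent_resistance_dyn_s_cm5 = r,
      P0_mmHg = P0_mmHg, V0_mm3 = V0_mm3,
      Ps_mmHg = Ps_mmHg, Pd_mmHg = Pd_mmHg
    ),
    class = "chamber_params"
  )
}

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 8 * mu * l / (pi * r^4)` for laminar flow in a rigid tube: linear in
#' viscosity and length, inverse fourth power in radius. Vectorised over
#' `l` and `r`.
#'
#' @param mu dynamic viscosity, poise.
#' @param l segment length, cm.
#' @param r mean lumen radius, cm (for a stenosed segment, the mean radius
#'   along the stenosis).
#' @return Resistance in dyn.s/cm5.
#' @export
poiseuille_resistance <- function(mu, l, r) {
  if (!all(is.finite(mu)) || any(mu <= 0)) value_error("viscosity must be positive")
  if (!all(is.finite(l)) || any(l <= 0)) value_error("length must be positive")
  if (!all(is.finite(r))) value_error("radius must be finite")
  if (any(r == 0)) value_error("radius 0 gives infinite resistance")
  if (any(r < 0)) value_error("radius must be positive")
  8 * mu * l / (pi * r^4)
}

#' Impedance magnitude of a parallel RC element
#'
#' `Z = 1 / sqrt((1/R)^2 + (2*pi*C/Tc)^2)`: the magnitude of a resistance in
#' parallel with a compliance at the fundamental cardiac frequency. `Z <= R`
#' always; `Z -> R` as `C -> 0` and `Z -> Tc/(2*pi*C)` as `R -> Inf`.
#'
#' @param R resistance, dyn.s/cm5.
#' @param C volume compliance, cm5/dyn.
#' @param Tc cardiac period, s.
#' @return Impedance magnitude in dyn.s/cm5. Vectorised.
#' @export
impedance <- function(R, C, Tc) {
  if (!all(is.finite(R)) || any(R <= 0)) value_error("R must be positive")
  if (!all(is.finite(C)) || any(C < 0)) value_error("C must be non-negative")
  if (!all(is.finite(Tc)) || any(Tc <= 0)) value_error("Tc must be positive")
  1 / sqrt((1 / R)^2 + (2 * pi * C / Tc)^2)
}

#' Trapped-gas compliance of a collection chamber
#'
#' Boyle's-law compliance of the air cushion in a collection chamber,
#' eliminating the systolic/diastolic volumes:
#' `C = P0 * V0 * (1/Pd - 1/Ps) / (Ps - Pd)`.
#'
#' @param P0 initial chamber pressure, mmHg (atmospheric, 760).
#' @param V0 initial trapped-gas volume, mm^3.
#' @param Ps,Pd systolic and diastolic chamber pressures, mmHg.
#' @return Compliance in mm^3/mmHg (convert with
#'   [chamber_compliance_cgs()] before circuit use).
#' @export
chamber_compliance <- function(P0, V0, Ps, Pd) {
  check_positive_scalar(P0, "P0")
  check_positive_scalar(V0, "V0")
  check_positive_scalar(Ps, "Ps")
  check_positive_scalar(Pd, "Pd")
  if (Ps <= Pd) value_error("Ps must exceed Pd (zero/negative pulse pressure)")
  P0 * V0 * (1 / Pd - 1 / Ps) / (Ps - Pd)
}

#' Convert a chamber compliance from mm^3/mmHg to CGS volume compliance
#'
#' @param compliance_mm3_mmHg compliance in mm^3/mmHg.
#' @return Compliance in cm5/dyn (cm^3 per dyn/cm2).
#' @export
chamber_compliance_cgs <- function(compliance_mm3_mmHg) {
  compliance_mm3_mmHg * 1e-3 / MMHG_TO_DYN_CM2
}

#' Volume compliance of a vessel segment from material area compliance
#'
#' Area compliance (lumen cross-section change per unit pressure) times
#' length gives volume compliance; converted to CGS
#' (1 mm^2 = 0.01 cm^2, 1 mmHg = 1333.22 dyn/cm2).
#'
#' @param area_compliance_mm2_mmHg material area compliance, mm^2/mmHg.
#' @param length_cm segment length, cm.
#' @return Volume compliance in cm5/dyn. Vectorised over `length_cm`.
#' @export
segment_compliance <- function(area_compliance_mm2_mmHg, length_cm) {
  if (!all(is.finite(area_compliance_mm2_mmHg)) || any(area_compliance_mm2_mmHg < 0)) {
    value_error("area compliance must be non-negative")
  }
  if (!all(is.finite(length_cm)) || any(length_cm < 0)) {
    value_error("length must be non-negative")
  }
  area_compliance_mm2_mmHg * 0.01 * length_cm / MMHG_TO_DYN_CM2
}

#' Convert pressures between mmHg and dyn/cm2
#'
#' @param value numeric vector of pressures.
#' @param from,to `"mmHg"` or `"dyn_cm2"`.
#' @return Converted pressures; round trip is the identity.
#' @export
convert_pressure <- function(value, from, to) {
  units <- c("mmHg", "dyn_cm2")
  if (!is.character(from) || length(from) != 1L || !from %in% units) {
    value_error("unknown pressure unit in `from`")
  }
  if (!is.character(to) || length(to) != 1L || !to %in% units) {
    value_error("unknown pressure unit in `to`")
  }
  if (!all(is.finite(value))) value_error("pressure values must be finite")
  if (from == to) return(value)
  if (from == "mmHg") value * MMHG_TO_DYN_CM2 else value / MMHG_TO_DYN_CM2
}

#' Load model parameters from a JSON config file
#'
#' The config mirrors [hemo_params()], [activity_state()] and
#' [chamber_params()] under keys `hemodynamics`, `activity_states` and
#' `chamber`; any key omitted falls back to the shipped default. The packaged
#' default config is at
#' `system.file("extdata", "params.default.json", package = "coroflow")`.
#'
#' @param path path to a JSON config, or `NULL` for the shipped defaults.
#' @return List with elements `params` (`hemo_params`), `states` (named list
#'   of `activity_state`) and `chamber` (`chamber_params`).
#' @export
load_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "params.default.json", package = "coroflow")
  }
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  cfg <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) format_error(sprintf("cannot parse config %s: %s", path, conditionMessage(e)))
  )
  hemo <- cfg$hemodynamics %||% list()
  params <- do.call(hemo_params, hemo)
  states <- if (is.null(cfg$activity_states)) {
    default_activity_states()
  } else {
    sts <- lapply(names(cfg$activity_states), function(nm) {
      activity_state(nm, unlist(cfg$activity_states[[nm]]))
    })
    names(sts) <- names(cfg$activity_states)
    validate_activity_states(sts)
    sts[order(match(names(sts), ACTIVITY_LEVELS))]
  }
  ch <- cfg$chamber %||% list()
  if (!is.null(ch$inherent_resistance_dyn_s_cm5)) {
    ch$inherent_resistance_dyn_s_cm5 <- unlist(ch$inherent_resistance_dyn_s_cm5)
  }
  chamber <- do.call(chamber_params, ch)
  list(params = params, states = states, chamber = chamber)
}
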