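# Seedable generator of patient-like coronary trees and noisy invasive /
# benchtop measurements. Emulates the study conditions: five patients, main
# vessels 3-5 mm in diameter, diseased LAD and LCX each carrying one stenosis
# with a pressure-wire measurement site just distal to it, healthy RCA with
# no measurement site. Daughter branches follow Murray-law tapering
# (r_child = r_parent * 2^(-1/3)) and attach distal to the measurement site,
# so the ostium-to-site path is branch-free and the invasive derivation sees
# the same series impedance the network does.

run_seeded <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

check_range <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 2L || !all(is.finite(x)) || x[1] > x[2] ||
      x[1] < lo || x[2] > hi) {
    value_error(sprintf("`%s` must be an ordered range within [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

#' Synthetic-cohort configuration
#'
#' Study conditions for the generator. Lesion severity is expressed as the
#' hyperemic (E2-state) distal/aortic pressure-ratio target per diseased
#' artery, emulating a catheterisation cohort dominated by hemodynamically
#' significant disease (all LAD lesions significant, LCX mixed); the solved
#' stenosis radius is clamped to the admissible radius-reduction bounds, with
#' lesion-length extension (diffuse disease) when a large vessel cannot reach
#' its target severity within those bounds. Setting
#' `stenosis_radius_reduction` to a scalar switches to a fixed fractional
#' radius reduction instead of severity targeting.
#'
#' @param n_models number of synthetic patients (default 5).
#' @param seed base RNG seed; every generated artefact is a pure function of
#'   `(seed, model_index)`.
#' @param main_diameter_range_mm main-vessel diameter range, mm.
#' @param daughter_count_range daughters per main artery (inclusive range).
#' @param length_range_cm branch-segment length range, cm.
#' @param stenosis_radius_reduction optional scalar fractional radius
#'   reduction in `stenosis_reduction_bounds`; `NULL` (default) enables
#'   severity targeting.
#' @param stenosis_reduction_bounds admissible fractional radius reduction.
#' @param stenosis_length_range_cm lesion length range, cm.
#' @param target_distal_ratio_lad,target_distal_ratio_lcx hyperemic
#'   distal/aortic pressure-ratio target ranges for the LAD and LCX lesions.
#' @param ffr_noise_sd additive Gaussian noise SD on the invasive FFR reading.
#' @param pressure_noise_sd_mmHg additive Gaussian noise SD on the benchtop
#'   distal pressure, mmHg.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_models = 5L,
                         seed = 1L,
                         main_diameter_range_mm = c(3, 5),
                         daughter_count_range = c(2L, 5L),
                         length_range_cm = c(2, 12),
                         stenosis_radius_reduction = NULL,
                         stenosis_reduction_bounds = c(0.2, 0.7),
                         stenosis_length_range_cm = c(1, 3),
                         target_distal_ratio_lad = c(0.55, 0.75),
                         target_distal_ratio_lcx = c(0.60, 0.82),
                         ffr_noise_sd = 0.03,
                         pressure_noise_sd_mmHg = 2.0) {
  if (!is.numeric(n_models) || length(n_models) != 1L || n_models < 1) {
    value_error("n_models must be >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    value_error("seed must be a single integer")
  }
  check_range(main_diameter_range_mm, "main_diameter_range_mm", 0.5, 10)
  check_range(daughter_count_range, "daughter_count_range", 0, 10)
  check_range(length_range_cm, "length_range_cm", 0.1, 50)
  check_range(stenosis_reduction_bounds, "stenosis_reduction_bounds", 0, 1)
  check_range(stenosis_length_range_cm, "stenosis_length_range_cm", 0.1, 10)
  check_range(target_distal_ratio_lad, "target_distal_ratio_lad", 0.1, 1)
  check_range(target_distal_ratio_lcx, "target_distal_ratio_lcx", 0.1, 1)
  if (!is.null(stenosis_radius_reduction)) {
    if (!is.numeric(stenosis_radius_reduction) ||
        length(stenosis_radius_reduction) != 1L ||
        stenosis_radius_reduction < stenosis_reduction_bounds[1] ||
        stenosis_radius_reduction > stenosis_reduction_bounds[2]) {
      value_error("stenosis_radius_reduction must lie in stenosis_reduction_bounds")
    }
  }
  if (ffr_noise_sd < 0 || pressure_noise_sd_mmHg < 0) {
    value_error("noise SDs must be non-negative")
  }
  structure(
    list(
      n_models = as.integer(n_models), seed = as.integer(seed),
      main_diameter_range_mm = main_diameter_range_mm,
      daughter_count_range = as.integer(daughter_count_range),
      length_range_cm = length_range_cm,
      stenosis_radius_reduction = stenosis_radius_reduction,
      stenosis_reduction_bounds = stenosis_reduction_bounds,
      stenosis_length_range_cm = stenosis_length_range_cm,
      target_distal_ratio_lad = target_distal_ratio_lad,
      target_distal_ratio_lcx = target_distal_ratio_lcx,
      ffr_noise_sd = ffr_noise_sd,
      pressure_noise_sd_mmHg = pressure_noise_sd_mmHg
    ),
    class = "synth_config"
  )
}

MURRAY_TAPER <- 2^(-1 / 3)

segment_df <- function(id, parent, artery, l, r, sten = FALSE, site = FALSE,
                       dist = NA_real_) {
  data.frame(segment_id = id, parent_id = parent, artery = artery,
             length_cm = l, mean_radius_cm = r, has_stenosis = sten,
             is_measurement_site = site, site_distance_cm = dist,
             stringsAsFactors = FALSE)
}

# branching continuation distal to `parent`: a chain of n_d main segments,
# one Murray-tapered daughter leaf hanging off each chain node
distal_branches <- function(prefix, parent, artery, r_main, n_d, len_range) {
  rows <- list()
  prev <- parent
  for (i in seq_len(n_d)) {
    m_id <- sprintf("%s_m%d", prefix, i)
    rows[[length(rows) + 1L]] <- segment_df(
      m_id, prev, artery, stats::runif(1, len_range[1], len_range[2]), r_main
    )
    rows[[length(rows) + 1L]] <- segment_df(
      sprintf("%s_d%d", prefix, i), m_id, artery,
      stats::runif(1, len_range[1], len_range[2]), r_main * MURRAY_TAPER
    )
    prev <- m_id
  }
  do.call(rbind, rows)
}

# distal/aortic pressure ratio at `site` for one artery standing alone,
# under the given activity state
artery_site_ratio <- function(seg, site, params, chamber, state) {
  sub_chamber <- chamber
  a <- seg$artery[1]
  sub_chamber$inherent_resistance_dyn_s_cm5 <-
    chamber$inherent_resistance_dyn_s_cm5[a]
  net <- build_network(coronary_tree(seg), params, state, sub_chamber,
                       include_outlet = FALSE)
  sol <- nodal_solve(net, params$mean_aortic_pressure_dyn_cm2)
  model_ffr(sol, site)
}

# solve the stenosis radius (and, if the reduction bound binds, the lesion
# length) so the artery hits its hyperemic severity target
fit_stenosis <- function(seg, sten_id, site_id, target, config, params,
                         chamber, hyperemic) {
  i <- match(sten_id, seg$segment_id)
  r_main <- seg$mean_radius_cm[match(seg$parent_id[i], seg$segment_id)]
  bounds <- config$stenosis_reduction_bounds
  r_lo <- r_main * (1 - bounds[2])
  r_hi <- r_main * (1 - bounds[1])
  f_r <- function(r) {
    seg$mean_radius_cm[i] <- r
    artery_site_ratio(seg, site_id, params, chamber, hyperemic) - target
  }
  if (f_r(r_hi) < 0) {
    seg$mean_radius_cm[i] <- r_hi          # even the mildest lesion overshoots
  } else if (f_r(r_lo) > 0) {
    # tightest admissible radius is still too mild: lengthen the lesion
    seg$mean_radius_cm[i] <- r_lo
    f_l <- function(l) {
      seg$length_cm[i] <- l
      artery_site_ratio(seg, site_id, params, chamber, hyperemic) - target
    }
    l_max <- 8
    if (f_l(l_max) > 0) {
      seg$length_cm[i] <- l_max
    } else {
      seg$length_cm[i] <- stats::uniroot(f_l, c(seg$length_cm[i], l_max),
                                         tol = 1e-4)$root
    }
  } else {
    seg$mean_radius_cm[i] <- stats::uniroot(f_r, c(r_lo, r_hi),
                                            tol = 1e-5)$root
  }
  # measurement-site distance runs ostium to the site segment's distal end
  site_i <- match(site_id, seg$segment_id)
  seg$site_distance_cm[site_i] <- seg$length_cm[match(seg$parent_id[i], seg$segment_id)] +
    seg$length_cm[i] + seg$length_cm[site_i]
  seg
}

diseased_artery <- function(artery, r_main, target, config, params, chamber,
                            hyperemic) {
  len_range <- config$length_range_cm
  prox <- segment_df(paste0(artery, "_prox"), NA_character_, artery,
                     stats::runif(1, 2, 5), r_main)
  l_sten <- stats::runif(1, config$stenosis_length_range_cm[1],
                         config$stenosis_length_range_cm[2])
  sten <- segment_df(paste0(artery, "_sten"), paste0(artery, "_prox"), artery,
                     l_sten, r_main * 0.5, sten = TRUE)
  site <- segment_df(paste0(artery, "_site"), paste0(artery, "_sten"), artery,
                     stats::runif(1, 1, 2), r_main, site = TRUE, dist = 0)
  n_d <- sample(seq(config$daughter_count_range[1],
                    config$daughter_count_range[2]), 1L)
  seg <- rbind(prox, sten, site,
               distal_branches(artery, paste0(artery, "_site"), artery,
                               r_main, n_d, len_range))
  if (!is.null(config$stenosis_radius_reduction)) {
    i <- match(paste0(artery, "_sten"), seg$segment_id)
    seg$mean_radius_cm[i] <- r_main * (1 - config$stenosis_radius_reduction)
    site_i <- match(paste0(artery, "_site"), seg$segment_id)
    seg$site_distance_cm[site_i] <- sum(seg$length_cm[c(1L, i, site_i)])
    seg
  } else {
    fit_stenosis(seg, paste0(artery, "_sten"), paste0(artery, "_site"),
                 target, config, params, chamber, hyperemic)
  }
}

#' Generate one synthetic patient coronary tree
#'
#' Three main arteries with diameters drawn from the configured 3-5 mm range;
#' LAD and LCX each carry one stenosed segment with a measurement site just
#' distal to it, with severity set as described in [synth_config()]; the RCA
#' is healthy and unsampled. Deterministic given `(config$seed, model_index)`.
#'
#' @param config a [synth_config()].
#' @param model_index 1-based patient index.
#' @param params,chamber model parameters used when solving lesion severity
#'   (defaults [hemo_params()], [chamber_params()]).
#' @param hyperemic activity state at which severity targets are evaluated;
#'   default the E2 state of [default_activity_states()].
#' @return A [coronary_tree()] with attribute `"synth_seed"`.
#' @export
generate_tree <- function(config, model_index = 1L,
                          params = hemo_params(), chamber = chamber_params(),
                          hyperemic = default_activity_states()$E2) {
  stopifnot(inherits(config, "synth_config"))
  seed_i <- config$seed + 7919L * as.integer(model_index)
  run_seeded(seed_i, function() {
    r_range <- config$main_diameter_range_mm / 20  # mm diameter -> cm radius
    r_mains <- stats::setNames(stats::runif(3, r_range[1], r_range[2]),
                               ARTERY_LABELS)
    targets <- c(
      LAD = stats::runif(1, config$target_distal_ratio_lad[1],
                         config$target_distal_ratio_lad[2]),
      LCX = stats::runif(1, config$target_distal_ratio_lcx[1],
                         config$target_distal_ratio_lcx[2])
    )
    lad <- diseased_artery("LAD", r_mains[["LAD"]], targets[["LAD"]],
                           config, params, chamber, hyperemic)
    lcx <- diseased_artery("LCX", r_mains[["LCX"]], targets[["LCX"]],
                           config, params, chamber, hyperemic)
    n_d <- sample(seq(config$daughter_count_range[1],
                      config$daughter_count_range[2]), 1L)
    rca <- rbind(
      segment_df("RCA_prox", NA_character_, "RCA", stats::runif(1, 2, 5),
                 r_mains[["RCA"]]),
      distal_branches("RCA", "RCA_prox", "RCA", r_mains[["RCA"]], n_d,
                      config$length_range_cm)
    )
    tree <- coronary_tree(rbind(lad, lcx, rca))
    attr(tree, "synth_seed") <- seed_i
    attr(tree, "model_index") <- as.integer(model_index)
    tree
  })
}

#' Generate noisy synthetic measurements for a tree
#'
#' Ground truth comes from the solved Windkessel network per activity state:
#' the true distal pressure at each measurement site. The invasive FFR
#' reading is the true distal/aortic ratio plus Gaussian noise (clamped to
#' (0, 1.2]); the benchtop reading is the true distal pressure in mmHg plus
#' Gaussian noise, clamped to the physical range (0, aortic pressure]. With
#' both noise SDs zero the measurements equal the model predictions exactly.
#'
#' @param tree a `coronary_tree` (typically from [generate_tree()]).
#' @param config a [synth_config()] (noise SDs).
#' @param params,chamber model parameters.
#' @param states activity states to measure under.
#' @param seed RNG seed; defaults to the tree's generation seed + 1.
#' @return Measurement data frame (see [read_measurements()]).
#' @export
generate_measurements <- function(tree, config,
                                  params = hemo_params(),
                                  chamber = chamber_params(),
                                  states = default_activity_states(),
                                  seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- seed %||% ((attr(tree, "synth_seed") %||% config$seed) + 1L)
  sites <- measurement_sites(tree)
  run_seeded(seed, function() {
    rows <- list()
    for (state in states) {
      sim <- simulate_flow(tree, params, state, chamber)
      for (s in sites) {
        true_ratio <- model_ffr(sim$solution, s)
        true_mmHg <- true_ratio * params$mean_aortic_pressure_dyn_cm2 / MMHG_TO_DYN_CM2
        ffr <- true_ratio + stats::rnorm(1, 0, config$ffr_noise_sd)
        ffr <- min(max(ffr, 0.01), 1.2)
        pres <- true_mmHg + stats::rnorm(1, 0, config$pressure_noise_sd_mmHg)
        # a distal sensor cannot read above the aortic driving pressure
        pres <- min(max(pres, 1),
                    params$mean_aortic_pressure_dyn_cm2 / MMHG_TO_DYN_CM2)
        rows[[length(rows) + 1L]] <- data.frame(
          segment_id = s, activity = state$name,
          invasive_ffr = ffr, benchtop_distal_pressure_mmHg = pres,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic study dataset
#'
#' @param config a [synth_config()].
#' @param params,chamber,states model parameters and activity states.
#' @return List of class `synth_dataset`: `models` (per patient: `tree` and
#'   `measurements`) and a deterministic `manifest` (seed, config echo,
#'   package version).
#' @export
generate_dataset <- function(config,
                             params = hemo_params(),
                             chamber = chamber_params(),
                             states = default_activity_states()) {
  stopifnot(inherits(config, "synth_config"))
  models <- lapply(seq_len(config$n_models), function(i) {
    tree <- generate_tree(config, i, params, chamber,
                          hyperemic = states[[length(states)]])
    list(tree = tree,
         measurements = generate_measurements(tree, config, params, chamber, states))
  })
  names(models) <- sprintf("model_%d", seq_len(config$n_models))
  structure(
    list(models = models,
         manifest = list(
           seed = config$seed,
           n_models = config$n_models,
           config = unclass(config),
           package_version = as.character(utils::packageVersion("coroflow"))
         )),
    class = "synth_dataset"
  )
}

#' Run the full comparison study on a dataset
#'
#' Sweeps every model through all activity states, derives the invasive and
#' benchtop flows from its measurements, and row-binds the per-model reports
#' (column `model`), attaching the combined per-state totals as attribute
#' `"totals"`. Feed the result to [flow_summary_tables()],
#' [compare_methods()] or [mean_pairwise_pearson()].
#'
#' @param dataset a `synth_dataset` from [generate_dataset()].
#' @param params,chamber,states model parameters and activity states.
#' @return Combined `site_flow_report` with `model` column.
#' @export
run_study <- function(dataset,
                      params = hemo_params(),
                      chamber = chamber_params(),
                      states = default_activity_states()) {
  stopifnot(inherits(dataset, "synth_dataset"))
  reports <- list()
  totals <- list()
  for (nm in names(dataset$models)) {
    m <- dataset$models[[nm]]
    rep_m <- activity_sweep(m$tree, params, chamber, states,
                            measurements = m$measurements)
    tot <- attr(rep_m, "totals")
    tot$model <- nm
    totals[[nm]] <- tot
    rep_m <- as.data.frame(rep_m)
    rep_m$model <- nm
    reports[[nm]] <- rep_m
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  attr(out, "totals") <- do.call(rbind, c(totals, make.row.names = FALSE))
  class(out) <- c("site_flow_report", class(out))
  out
}
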