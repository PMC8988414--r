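# Electrical-equivalent network assembly and solution. The analysis is steady
# mean-flow on impedance magnitudes: every element is a scalar impedance in
# dyn*s/cm5, the aortic root is a fixed pressure source, the venous return is
# ground at 0 dyn/cm2. Solved two ways: exact series/parallel reduction and a
# general nodal (Kirchhoff) linear solve; the two are mutual oracles.

SOURCE_NODE <- "aorta"
GROUND_NODE <- "gnd"

#' Assemble the electrically equivalent network of a coronary tree
#'
#' One impedance element per vessel segment (Poiseuille resistance combined
#' with the segment's material compliance at the cardiac fundamental);
#' children of a branching node sit in parallel, each in series with its
#' parent. Every leaf of an artery drains into that artery's collection
#' chamber (inherent resistance in parallel with the Boyle's-law chamber
#' compliance, taken as one impedance element), followed in series by the
#' activity-state distal resistance to ground. An optional aortic outlet
#' resistor from source to ground carries the non-coronary flow and is sized
#' by [calibrate_outlet()].
#'
#' With `compliance_mode = "per_artery"` segments are pure resistors and the
#' artery's summed material compliance is lumped into its chamber capacitance.
#'
#' @param tree a [coronary_tree()].
#' @param params a [hemo_params()].
#' @param activity an [activity_state()].
#' @param chamber a [chamber_params()]. An artery the chamber expects but the
#'   tree lacks raises a configuration warning and its chamber is omitted.
#' @param include_outlet add the aortic outlet resistor (default `TRUE`).
#' @param outlet_resistance initial outlet resistance, dyn.s/cm5; default
#'   sizes it to pass the full target flow (then see [calibrate_outlet()]).
#' @return An object of class `circuit_network`: element table
#'   (`element_id`, `kind`, `Z_dyn_s_cm5`, `node_from`, `node_to`,
#'   `segment_id`), source and ground node ids, and the activity name.
#' @export
build_network <- function(tree, params, activity, chamber,
                          include_outlet = TRUE, outlet_resistance = NULL) {
  stopifnot(inherits(tree, "coronary_tree"), inherits(params, "hemo_params"),
            inherits(activity, "activity_state"), inherits(chamber, "chamber_params"))
  seg <- tree$segments
  Tc <- params$cardiac_period_s
  per_segment <- params$compliance_mode == "per_segment"

  R_seg <- poiseuille_resistance(params$viscosity_poise, seg$length_cm, seg$mean_radius_cm)
  C_seg <- if (per_segment) {
    segment_compliance(params$material_area_compliance_mm2_mmHg, seg$length_cm)
  } else {
    rep(0, nrow(seg))
  }
  Z_seg <- impedance(R_seg, C_seg, Tc)

  is_parent <- seg$segment_id %in% seg$parent_id[!is.na(seg$parent_id)]
  node_of <- ifelse(is_parent, paste0("n_", seg$segment_id),
                    paste0("chamber_in_", seg$artery))
  names(node_of) <- seg$segment_id
  from <- ifelse(is.na(seg$parent_id), SOURCE_NODE, node_of[seg$parent_id])

  el <- data.frame(
    element_id = paste0("seg_", seg$segment_id),
    kind = "impedance",
    Z_dyn_s_cm5 = Z_seg,
    node_from = unname(from),
    node_to = unname(node_of),
    segment_id = seg$segment_id,
    stringsAsFactors = FALSE
  )

  arteries_present <- intersect(ARTERY_LABELS, unique(seg$artery))
  C_ch_base <- chamber_compliance_cgs(
    chamber_compliance(chamber$P0_mmHg, chamber$V0_mm3,
                       chamber$Ps_mmHg, chamber$Pd_mmHg)
  )
  for (a in names(chamber$inherent_resistance_dyn_s_cm5)) {
    if (!a %in% arteries_present) {
      warn_coroflow(
        sprintf("artery %s has a configured chamber but no segments; chamber omitted", a),
        "coroflow_config_warning"
      )
      next
    }
    if (is.na(match(a, names(activity$distal_resistance_dyn_s_cm5)))) {
      value_error(sprintf("activity state lacks a distal resistance for artery %s", a))
    }
    C_ch <- C_ch_base
    if (!per_segment) {
      C_ch <- C_ch + sum(segment_compliance(params$material_area_compliance_mm2_mmHg,
                                            seg$length_cm[seg$artery == a]))
    }
    el <- rbind(el, data.frame(
      element_id = c(paste0("chamber_", a), paste0("distal_", a)),
      kind = c("impedance", "resistor"),
      Z_dyn_s_cm5 = c(
        impedance(chamber$inherent_resistance_dyn_s_cm5[[a]], C_ch, Tc),
        activity$distal_resistance_dyn_s_cm5[[a]]
      ),
      node_from = c(paste0("chamber_in_", a), paste0("distal_in_", a)),
      node_to = c(paste0("distal_in_", a), GROUND_NODE),
      segment_id = NA_character_,
      stringsAsFactors = FALSE
    ))
  }

  if (include_outlet) {
    r_out <- outlet_resistance %||%
      (params$mean_aortic_pressure_dyn_cm2 / params$total_input_flow_cc_s)
    el <- rbind(el, data.frame(
      element_id = "aortic_outlet", kind = "resistor", Z_dyn_s_cm5 = r_out,
      node_from = SOURCE_NODE, node_to = GROUND_NODE,
      segment_id = NA_character_, stringsAsFactors = FALSE
    ))
  }
  rownames(el) <- NULL
  if (any(!is.finite(el$Z_dyn_s_cm5)) || any(el$Z_dyn_s_cm5 <= 0)) {
    value_error("all passive elements must have positive finite impedance")
  }
  structure(
    list(elements = el, source_node = SOURCE_NODE, ground = GROUND_NODE,
         activity = activity$name),
    class = "circuit_network"
  )
}

#' @export
print.circuit_network <- function(x, ...) {
  cat(sprintf("<circuit_network> %d elements, activity %s\n",
              nrow(x$elements), x$activity))
  invisible(x)
}

#' Solve a network by nodal analysis
#'
#' Stamps the element conductances into the nodal admittance matrix, fixes
#' the source node at `source_pressure` and ground at 0, and solves the
#' linear Kirchhoff system for all internal node pressures and element flows.
#'
#' @param net a `circuit_network`.
#' @param source_pressure source (aortic) pressure in dyn/cm2.
#' @return An object of class `flow_solution`: the element table augmented
#'   with `flow_cc_s`, `upstream_pressure_dyn_cm2`,
#'   `downstream_pressure_dyn_cm2`, plus `node_pressures`, `source_pressure`
#'   and the activity name.
#' @export
nodal_solve <- function(net, source_pressure) {
  stopifnot(inherits(net, "circuit_network"))
  check_positive_scalar(source_pressure, "source_pressure")
  el <- net$elements
  nodes <- unique(c(el$node_from, el$node_to))
  if (!net$ground %in% nodes) topology_error("network has no path to ground")
  unknown <- setdiff(nodes, c(net$source_node, net$ground))
  g <- 1 / el$Z_dyn_s_cm5

  p <- stats::setNames(numeric(length(nodes)), nodes)
  p[net$source_node] <- source_pressure
  if (length(unknown)) {
    G <- matrix(0, length(unknown), length(unknown),
                dimnames = list(unknown, unknown))
    b <- stats::setNames(numeric(length(unknown)), unknown)
    ui <- match(el$node_from, unknown)
    vi <- match(el$node_to, unknown)
    for (k in seq_len(nrow(el))) {
      i <- ui[k]; j <- vi[k]
      if (!is.na(i)) G[i, i] <- G[i, i] + g[k]
      if (!is.na(j)) G[j, j] <- G[j, j] + g[k]
      if (!is.na(i) && !is.na(j)) {
        G[i, j] <- G[i, j] - g[k]
        G[j, i] <- G[j, i] - g[k]
      }
      if (is.na(i) && !is.na(j) && el$node_from[k] == net$source_node) {
        b[j] <- b[j] + g[k] * source_pressure
      }
      if (is.na(j) && !is.na(i) && el$node_to[k] == net$source_node) {
        b[i] <- b[i] + g[k] * source_pressure
      }
    }
    x <- tryCatch(solve(G, b), error = function(e) {
      topology_error("singular nodal system (disconnected network component)")
    })
    p[unknown] <- x
  }

  el$flow_cc_s <- (p[el$node_from] - p[el$node_to]) * g
  el$upstream_pressure_dyn_cm2 <- unname(p[el$node_from])
  el$downstream_pressure_dyn_cm2 <- unname(p[el$node_to])
  rownames(el) <- NULL
  structure(
    list(elements = el, node_pressures = p, source_pressure = source_pressure,
         activity = net$activity, source_node = net$source_node,
         ground = net$ground),
    class = "flow_solution"
  )
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> activity %s, source %.1f mmHg, total flow %.3f cc/s\n",
              x$activity, x$source_pressure / MMHG_TO_DYN_CM2, source_flow(x)))
  invisible(x)
}

#' Maximum Kirchhoff current-law residual of a solution
#'
#' Largest absolute net flow imbalance over internal nodes, relative to the
#' total source flow. Zero (to numerical precision) for any valid solution.
#'
#' @param solution a `flow_solution`.
#' @return Non-negative scalar.
#' @export
kcl_residual <- function(solution) {
  el <- solution$elements
  internal <- setdiff(names(solution$node_pressures),
                      c(solution$source_node, solution$ground))
  if (!length(internal)) return(0)
  net_in <- vapply(internal, function(nd) {
    sum(el$flow_cc_s[el$node_to == nd]) - sum(el$flow_cc_s[el$node_from == nd])
  }, numeric(1))
  max(abs(net_in)) / max(abs(source_flow(solution)), .Machine$double.eps)
}

#' Total flow leaving the source node
#' @param solution a `flow_solution`.
#' @return Flow in cc/s.
#' @export
source_flow <- function(solution) {
  el <- solution$elements
  sum(el$flow_cc_s[el$node_from == solution$source_node]) -
    sum(el$flow_cc_s[el$node_to == solution$source_node])
}

#' Total coronary inflow (source flow excluding the aortic outlet)
#' @param solution a `flow_solution`.
#' @return Flow in cc/s.
#' @export
coronary_inflow <- function(solution) {
  el <- solution$elements
  keep <- el$node_from == solution$source_node & el$element_id != "aortic_outlet"
  sum(el$flow_cc_s[keep])
}

#' Flow through the aortic outlet resistor
#' @param solution a `flow_solution`.
#' @return Flow in cc/s (0 when the network has no outlet).
#' @export
outlet_flow <- function(solution) {
  el <- solution$elements
  i <- match("aortic_outlet", el$element_id)
  if (is.na(i)) 0 else el$flow_cc_s[i]
}

#' Equivalent impedance seen by the source
#'
#' Reduces the passive network between source and ground by repeated
#' series/parallel merging (with pruning of dangling dead-end nodes, which
#' carry no current). Networks built from vessel trees always reduce fully;
#' a non-reducible topology falls back to the nodal solver's equivalent
#' (source pressure over total source current).
#'
#' @param net a `circuit_network`.
#' @param drop_elements element ids to exclude (e.g. `"aortic_outlet"` to get
#'   the coronary-only equivalent).
#' @return Equivalent impedance in dyn.s/cm5.
#' @export
reduce_network <- function(net, drop_elements = NULL) {
  stopifnot(inherits(net, "circuit_network"))
  el <- net$elements
  if (!is.null(drop_elements)) el <- el[!el$element_id %in% drop_elements, , drop = FALSE]
  if (nrow(el) == 0L) topology_error("no elements between source and ground")
  from <- el$node_from; to <- el$node_to; z <- el$Z_dyn_s_cm5
  src <- net$source_node; gnd <- net$ground

  repeat {
    changed <- FALSE

    # prune dangling internal nodes (degree 1): no current can flow
    repeat {
      deg <- table(c(from, to))
      dangling <- names(deg)[deg == 1 & !names(deg) %in% c(src, gnd)]
      if (!length(dangling)) break
      keep <- !(from %in% dangling | to %in% dangling)
      from <- from[keep]; to <- to[keep]; z <- z[keep]
      changed <- TRUE
    }
    if (!length(z)) topology_error("source and ground are not connected")

    # parallel: merge duplicate node pairs
    key <- ifelse(from < to, paste(from, to), paste(to, from))
    if (anyDuplicated(key)) {
      zp <- tapply(1 / z, key, sum)
      first <- !duplicated(key)
      from <- from[first]; to <- to[first]
      z <- as.numeric(1 / zp[key[first]])
      changed <- TRUE
    }

    # series: splice out internal degree-2 nodes
    deg <- table(c(from, to))
    mid <- names(deg)[deg == 2 & !names(deg) %in% c(src, gnd)]
    if (length(mid)) {
      nd <- mid[[1]]
      hit <- which(from == nd | to == nd)
      if (length(hit) == 2L) {
        a <- if (from[hit[1]] == nd) to[hit[1]] else from[hit[1]]
        b <- if (from[hit[2]] == nd) to[hit[2]] else from[hit[2]]
        znew <- z[hit[1]] + z[hit[2]]
        from <- c(from[-hit], a); to <- c(to[-hit], b); z <- c(z[-hit], znew)
        changed <- TRUE
      }
    }

    if (length(z) == 1L && ((from == src & to == gnd) || (from == gnd & to == src))) {
      return(z)
    }
    if (!changed) break
  }

  # fallback: nodal equivalent on the remaining (non-series/parallel) graph
  sub <- structure(
    list(elements = data.frame(element_id = sprintf("e%03d", seq_along(z)),
                               kind = "impedance", Z_dyn_s_cm5 = z,
                               node_from = from, node_to = to,
                               segment_id = NA_character_,
                               stringsAsFactors = FALSE),
         source_node = src, ground = gnd, activity = net$activity),
    class = "circuit_network"
  )
  sol <- nodal_solve(sub, 1)
  1 / source_flow(sol)
}

#' Calibrate the aortic outlet against the total input flow
#'
#' Sizes the outlet resistor so that the total source current equals the
#' configured total input flow at the configured source pressure, in closed
#' form: `1/R_out = I_target/P - 1/Z_coronary`. Errors if the coronary bed
#' alone already draws more than the target.
#'
#' @param net a `circuit_network` containing an `aortic_outlet` element.
#' @param params a [hemo_params()].
#' @return The network with the outlet resistance replaced.
#' @export
calibrate_outlet <- function(net, params) {
  stopifnot(inherits(net, "circuit_network"), inherits(params, "hemo_params"))
  i <- match("aortic_outlet", net$elements$element_id)
  if (is.na(i)) state_error("network has no aortic outlet element to calibrate")
  P <- params$mean_aortic_pressure_dyn_cm2
  I_target <- params$total_input_flow_cc_s
  Z_cor <- reduce_network(net, drop_elements = "aortic_outlet")
  I_cor <- P / Z_cor
  if (I_cor >= I_target) {
    calibration_error(sprintf(
      "coronary flow alone (%.4g cc/s) meets or exceeds the %.4g cc/s target (excess %.4g)",
      I_cor, I_target, I_cor - I_target
    ))
  }
  net$elements$Z_dyn_s_cm5[i] <- 1 / (I_target / P - 1 / Z_cor)
  net
}

#' Build, calibrate and solve in one call
#'
#' @param tree a [coronary_tree()].
#' @param params a [hemo_params()].
#' @param activity an [activity_state()].
#' @param chamber a [chamber_params()].
#' @param calibrate calibrate the aortic outlet to the total input flow
#'   (default `TRUE`).
#' @param include_outlet include the aortic outlet resistor.
#' @return List with elements `network` and `solution`.
#' @export
simulate_flow <- function(tree, params, activity, chamber,
                          calibrate = TRUE, include_outlet = TRUE) {
  net <- build_network(tree, params, activity, chamber,
                       include_outlet = include_outlet)
  if (calibrate && include_outlet) net <- calibrate_outlet(net, params)
  list(network = net,
       solution = nodal_solve(net, params$mean_aortic_pressure_dyn_cm2))
}

#' Write a flow solution to CSV
#'
#' Columns: `element_id,segment_id,flow_cc_s,upstream_pressure_dyn_cm2,downstream_pressure_dyn_cm2`.
#'
#' @param solution a `flow_solution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  stopifnot(inherits(solution, "flow_solution"))
  el <- solution$elements
  out <- data.frame(
    element_id = el$element_id,
    segment_id = ifelse(is.na(el$segment_id), "", el$segment_id),
    flow_cc_s = el$flow_cc_s,
    upstream_pressure_dyn_cm2 = el$upstream_pressure_dyn_cm2,
    downstream_pressure_dyn_cm2 = el$downstream_pressure_dyn_cm2,
    stringsAsFactors = FALSE
  )
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
           error = function(e) io_error(sprintf("cannot write %s", path)))
  invisible(path)
}
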