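test_that("a single-segment artery builds a three-element series chain", {
  s <- default_setup()
  net <- build_network(single_segment_tree(), s$params, s$states$R,
                       chamber_params(inherent_resistance_dyn_s_cm5 = c(LAD = 1671)),
                       include_outlet = FALSE)
  el <- net$elements
  expect_equal(nrow(el), 3L)
  expect_setequal(el$element_id, c("seg_LAD1", "chamber_LAD", "distal_LAD"))
  # series chain: equivalent impedance is the plain sum
  expect_equal(reduce_network(net), sum(el$Z_dyn_s_cm5), tolerance = 1e-12)
})

test_that("element count follows segments + per-artery boundary + outlet", {
  s <- default_setup()
  tree <- example_tree()
  net <- build_network(tree, s$params, s$states$E1, s$chamber)
  expect_equal(nrow(net$elements), n_segments(tree) + 3L * 2L + 1L)
})

test_that("a chamber without its artery is dropped with a warning", {
  s <- default_setup()
  tree <- single_segment_tree()  # LAD only
  w <- testthat::capture_warnings(
    net <- build_network(tree, s$params, s$states$R, s$chamber,
                         include_outlet = FALSE)
  )
  expect_length(w, 2L)  # one per absent artery (LCX, RCA)
  expect_true(all(grepl("chamber omitted", w)))
  expect_false(any(grepl("RCA|LCX", net$elements$element_id)))
})

test_that("nodal solution obeys Ohm's law and Kirchhoff's laws", {
  s <- default_setup()
  # single resistor: flow = P/R
  net <- build_network(single_segment_tree(), s$params, s$states$R,
                       chamber_params(inherent_resistance_dyn_s_cm5 = c(LAD = 1671)),
                       include_outlet = FALSE)
  sol <- nodal_solve(net, 133322)
  Z_tot <- sum(net$elements$Z_dyn_s_cm5)
  expect_equal(source_flow(sol), 133322 / Z_tot, tolerance = 1e-12)
  # series conservation: identical flow in every chain element
  expect_equal(diff(range(sol$elements$flow_cc_s)), 0, tolerance = 1e-12)

  tree <- example_tree()
  sol2 <- simulate_flow(tree, s$params, s$states$E2, s$chamber)$solution
  expect_lt(kcl_residual(sol2), 1e-9)
  # passive network: all node pressures between ground and source
  expect_true(all(sol2$node_pressures >= -1e-9))
  expect_true(all(sol2$node_pressures <= 133322 * (1 + 1e-12)))
})

test_that("hand series/parallel algebra matches the solver on a bifurcation", {
  s <- default_setup()
  tree <- bifurcation_tree()
  ch <- chamber_params(inherent_resistance_dyn_s_cm5 = c(LAD = 1671))
  net <- build_network(tree, s$params, s$states$R, ch, include_outlet = FALSE)
  el <- net$elements
  z <- stats::setNames(el$Z_dyn_s_cm5, el$element_id)
  # children in parallel, in series with parent and the boundary pair
  z_hand <- z[["seg_LAD1"]] +
    1 / (1 / z[["seg_LAD2a"]] + 1 / z[["seg_LAD2b"]]) +
    z[["chamber_LAD"]] + z[["distal_LAD"]]
  expect_equal(reduce_network(net), unname(z_hand), tolerance = 1e-12)
  # per-element flows agree with back-substitution through the divider
  sol <- nodal_solve(net, 133322)
  i_tot <- 133322 / z_hand
  drop_par <- i_tot / (1 / z[["seg_LAD2a"]] + 1 / z[["seg_LAD2b"]])
  f <- stats::setNames(sol$elements$flow_cc_s, sol$elements$element_id)
  expect_equal(unname(f[["seg_LAD1"]]), unname(i_tot), tolerance = 1e-12)
  expect_equal(unname(f[["seg_LAD2a"]]), unname(drop_par / z[["seg_LAD2a"]]),
               tolerance = 1e-12)
  expect_equal(unname(f[["seg_LAD2b"]]), unname(drop_par / z[["seg_LAD2b"]]),
               tolerance = 1e-12)
})

test_that("trivial parallel and series resistor combinations reduce exactly", {
  mk <- function(from, to, z) {
    structure(list(
      elements = data.frame(
        element_id = sprintf("e%d", seq_along(z)), kind = "resistor",
        Z_dyn_s_cm5 = z, node_from = from, node_to = to,
        segment_id = NA_character_, stringsAsFactors = FALSE),
      source_node = "aorta", ground = "gnd", activity = "R"),
      class = "circuit_network")
  }
  expect_equal(reduce_network(mk(c("aorta", "aorta"), c("gnd", "gnd"), c(100, 100))), 50)
  expect_equal(reduce_network(mk(c("aorta", "x"), c("x", "gnd"), c(70, 30))), 100)
})

test_that("series/parallel reduction agrees with the nodal solver on random trees", {
  set.seed(99)
  s <- default_setup()
  worst <- 0
  for (i in 1:200) {
    tree <- random_tree(sample(3:30, 1))
    net <- build_network(tree, s$params,
                         s$states[[sample(c("R", "E1", "E2"), 1)]], s$chamber)
    z_red <- reduce_network(net)
    sol <- nodal_solve(net, 133322)
    z_nodal <- 133322 / source_flow(sol)
    worst <- max(worst, abs(z_red - z_nodal) / z_nodal)
  }
  expect_lt(worst, 1e-9)
})

test_that("outlet calibration hits the configured total flow in closed form", {
  s <- default_setup()
  tree <- example_tree()
  for (st in s$states) {
    net <- calibrate_outlet(build_network(tree, s$params, st, s$chamber), s$params)
    sol <- nodal_solve(net, s$params$mean_aortic_pressure_dyn_cm2)
    expect_equal(source_flow(sol), 8.33, tolerance = 1e-9)
    expect_equal(coronary_inflow(sol) + outlet_flow(sol), 8.33, tolerance = 1e-9)
  }
  # symmetric split: coronary impedance exactly twice P/I -> R_out equals it
  p_sym <- hemo_params(total_input_flow_cc_s = 8.33)
  z_target <- p_sym$mean_aortic_pressure_dyn_cm2 / 8.33
  net_sym <- structure(list(
    elements = data.frame(
      element_id = c("seg_X", "aortic_outlet"), kind = "resistor",
      Z_dyn_s_cm5 = c(2 * z_target, 1), node_from = "aorta", node_to = "gnd",
      segment_id = c("X", NA), stringsAsFactors = FALSE),
    source_node = "aorta", ground = "gnd", activity = "R"),
    class = "circuit_network")
  cal <- calibrate_outlet(net_sym, p_sym)
  expect_equal(cal$elements$Z_dyn_s_cm5[2], 2 * z_target, tolerance = 1e-12)
})

test_that("an infeasible calibration target raises a calibration error", {
  # distal resistances at the catheter minimum and a huge target drop
  p <- hemo_params(total_input_flow_cc_s = 0.5)
  s <- default_setup()
  tree <- example_tree()
  net <- build_network(tree, p, s$states$E2, s$chamber)
  expect_error(calibrate_outlet(net, p), class = "coroflow_calibration_error")
})

test_that("lowering distal resistance raises artery inflow monotonically", {
  s <- default_setup()
  tree <- example_tree()
  inflow <- vapply(s$states, function(st) {
    coronary_inflow(simulate_flow(tree, s$params, st, s$chamber)$solution)
  }, numeric(1))
  expect_true(inflow[["R"]] < inflow[["E1"]] && inflow[["E1"]] < inflow[["E2"]])
})

test_that("tightening a stenosis strictly reduces flow along its path", {
  s <- default_setup()
  radii <- c(0.08, 0.06, 0.045)
  flows <- vapply(radii, function(r) {
    df <- example_tree_df()
    df$mean_radius_cm[df$segment_id == "LAD_sten"] <- r
    sol <- simulate_flow(coronary_tree(df), s$params, s$states$E2, s$chamber)$solution
    windkessel_site_flow(sol, coronary_tree(df), "LAD_site")
  }, numeric(1))
  expect_true(all(diff(flows) < 0))
})

test_that("a disconnected network is reported as a topology error", {
  net <- structure(list(
    elements = data.frame(
      element_id = "e1", kind = "resistor", Z_dyn_s_cm5 = 10,
      node_from = "aorta", node_to = "island",
      segment_id = NA_character_, stringsAsFactors = FALSE),
    source_node = "aorta", ground = "gnd", activity = "R"),
    class = "circuit_network")
  expect_error(nodal_solve(net, 100), class = "coroflow_topology_error")
})

test_that("solution CSV export carries flows and node pressures per element", {
  s <- default_setup()
  sol <- simulate_flow(example_tree(), s$params, s$states$R, s$chamber)$solution
  f <- withr::local_tempfile(fileext = ".csv")
  write_solution_csv(sol, f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), nrow(sol$elements))
  expect_equal(got$flow_cc_s, sol$elements$flow_cc_s, tolerance = 1e-9)
})
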