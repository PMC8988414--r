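test_that("site flow equals artery inflow on a branch-free path", {
  s <- default_setup()
  tree <- example_tree()
  sol <- simulate_flow(tree, s$params, s$states$E1, s$chamber)$solution
  # LAD path to the site has no take-offs: site flow = LAD root element flow
  f_root <- sol$elements$flow_cc_s[sol$elements$element_id == "seg_LAD_prox"]
  expect_equal(windkessel_site_flow(sol, tree, "LAD_site"), f_root,
               tolerance = 1e-12)
  # site flow equals the sum of its child flows (Kirchhoff at the site node)
  f_site <- sol$elements$flow_cc_s[sol$elements$element_id == "seg_LAD_site"]
  kids <- sol$elements$flow_cc_s[sol$elements$element_id == "seg_LAD_d1"]
  expect_equal(f_site, kids, tolerance = 1e-12)
  expect_error(windkessel_site_flow(sol, tree, "LAD_d1"),
               class = "coroflow_lookup_error")
  expect_error(windkessel_site_flow(sim <- "not a solution", tree, "LAD_site"),
               class = "coroflow_state_error")
})

test_that("invasive flow follows (1-ffr)*Pa over the path impedance", {
  # C = 0 so the path impedance is the plain Poiseuille sum: pick geometry
  # giving exactly 50000 dyn.s/cm5, then check the textbook value 0.533 cc/s
  p0 <- hemo_params(material_area_compliance_mm2_mmHg = 1e-12)
  r <- (8 * p0$viscosity_poise * 10 / (pi * 50000))^(1 / 4)
  tree <- coronary_tree(seg_row("LAD1", NA_character_, "LAD", 10, r,
                                site = TRUE, dist = 10))
  z <- path_impedance(tree, p0, "LAD1")
  expect_equal(z, 50000, tolerance = 1e-9)
  expect_equal(invasive_site_flow(0.8, p0, tree, "LAD1"),
               0.2 * 133322 / 50000, tolerance = 1e-9)
  # no gradient at ffr = 1
  expect_equal(invasive_site_flow(1, p0, tree, "LAD1"), 0)
  # halving the path resistance doubles the flow at fixed ffr
  tree2 <- coronary_tree(seg_row("LAD1", NA_character_, "LAD", 5, r,
                                 site = TRUE, dist = 5))
  expect_equal(invasive_site_flow(0.8, p0, tree2, "LAD1"),
               2 * invasive_site_flow(0.8, p0, tree, "LAD1"),
               tolerance = 1e-9)
  # out-of-range and clamped readings
  expect_error(invasive_site_flow(1.3, p0, tree, "LAD1"),
               class = "coroflow_value_error")
  expect_error(invasive_site_flow(0, p0, tree, "LAD1"),
               class = "coroflow_value_error")
  expect_warning(f <- invasive_site_flow(1.05, p0, tree, "LAD1"),
                 class = "coroflow_clamp_warning")
  expect_equal(f, 0)
})

test_that("benchtop flow equals the invasive flow at the matching pressure", {
  s <- default_setup()
  tree <- example_tree()
  for (ffr in c(0.55, 0.8, 0.97)) {
    expect_equal(
      benchtop_site_flow(ffr * 100, s$params, tree, "LCX_site"),
      invasive_site_flow(ffr, s$params, tree, "LCX_site"),
      tolerance = 1e-12
    )
  }
  expect_equal(benchtop_site_flow(100, s$params, tree, "LCX_site"), 0)
  expect_error(benchtop_site_flow(120, s$params, tree, "LCX_site"),
               class = "coroflow_value_error")
  expect_error(benchtop_site_flow(-5, s$params, tree, "LCX_site"),
               class = "coroflow_value_error")
})

test_that("model pressure ratio behaves as a voltage divider", {
  s <- default_setup()
  # equal series impedances above and below the site node -> ratio 0.5
  p0 <- hemo_params(material_area_compliance_mm2_mmHg = 1e-12)
  tree <- single_segment_tree(l = 10, r = 0.1)
  R_seg <- poiseuille_resistance(p0$viscosity_poise, 10, 0.1)
  ch <- chamber_params(inherent_resistance_dyn_s_cm5 = c(LAD = 1671))
  # choose a legal distal resistance, then measure against hand algebra
  st <- activity_state("R", c(LAD = 250000))
  net <- build_network(tree, p0, st, ch, include_outlet = FALSE)
  sol <- nodal_solve(net, 133322)
  z <- stats::setNames(net$elements$Z_dyn_s_cm5, net$elements$element_id)
  expected <- (z[["chamber_LAD"]] + z[["distal_LAD"]]) / sum(z)
  expect_equal(model_ffr(sol, "LAD1"), unname(expected), tolerance = 1e-12)

  # tighter stenosis -> lower ratio
  ratios <- vapply(c(0.08, 0.06, 0.045), function(r) {
    df <- example_tree_df()
    df$mean_radius_cm[df$segment_id == "LAD_sten"] <- r
    tr <- coronary_tree(df)
    model_ffr(simulate_flow(tr, s$params, s$states$E2, s$chamber)$solution,
              "LAD_site")
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("feeding model distal pressure back recovers the model flow", {
  s <- default_setup()
  tree <- example_tree()
  for (st in s$states) {
    sol <- simulate_flow(tree, s$params, st, s$chamber)$solution
    for (site in measurement_sites(tree)) {
      p_mmHg <- model_ffr(sol, site) * s$params$mean_aortic_pressure_dyn_cm2 / 1333.22
      expect_equal(benchtop_site_flow(p_mmHg, s$params, tree, site),
                   windkessel_site_flow(sol, tree, site),
                   tolerance = 1e-6)
    }
  }
})

test_that("activity sweep produces one report row per site and state", {
  s <- default_setup()
  tree <- example_tree()
  report <- activity_sweep(tree, s$params, s$chamber, s$states)
  expect_equal(nrow(report), 6L)
  expect_equal(sort(unique(report$activity)), sort(c("R", "E1", "E2")))
  # model flow rises strictly with activity at every site
  for (site in unique(report$site)) {
    keep <- report$site == site
    w <- report$I_windkessel_cc_s[keep][order(match(report$activity[keep], c("R", "E1", "E2")))]
    expect_true(all(diff(w) > 0))
  }
  tot <- attr(report, "totals")
  expect_equal(tot$total_cc_s, rep(8.33, 3), tolerance = 1e-9)

  empty <- activity_sweep(tree, s$params, s$chamber, s$states, sites = character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("measurement and report CSV dialects round-trip", {
  meas <- data.frame(
    segment_id = c("LAD_site", "LCX_site"), activity = c("R", "E2"),
    invasive_ffr = c(0.82, NA), benchtop_distal_pressure_mmHg = c(NA, 71.3),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(meas, f)
  expect_identical(read_measurements(f), meas)

  s <- default_setup()
  report <- activity_sweep(example_tree(), s$params, s$chamber, s$states)
  fr <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(report, fr)
  back <- read_report_csv(fr)
  expect_equal(back$I_windkessel_cc_s, report$I_windkessel_cc_s, tolerance = 1e-15)
  expect_equal(back$model_ffr, report$model_ffr, tolerance = 1e-15)

  # a measurement row with neither reading is invalid
  writeLines(c("segment_id,activity,invasive_ffr,benchtop_distal_pressure_mmHg",
               "LAD_site,R,,"), f)
  expect_error(read_measurements(f), class = "coroflow_value_error")
})
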