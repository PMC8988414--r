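test_that("Poiseuille resistance matches direct arithmetic and its scalings", {
  # direct arithmetic oracle: 8*mu*l/(pi*r^4)
  expect_equal(poiseuille_resistance(0.037, 10, 0.15),
               8 * 0.037 * 10 / (pi * 0.15^4), tolerance = 1e-12)
  # doubling the radius divides resistance by exactly 16
  expect_identical(poiseuille_resistance(0.037, 5, 0.1) /
                     poiseuille_resistance(0.037, 5, 0.2), 16)
  # series additivity in length, linearity in viscosity
  expect_equal(poiseuille_resistance(0.037, 3 + 4, 0.12),
               poiseuille_resistance(0.037, 3, 0.12) +
                 poiseuille_resistance(0.037, 4, 0.12))
  expect_equal(poiseuille_resistance(2 * 0.037, 3, 0.12),
               2 * poiseuille_resistance(0.037, 3, 0.12))
  expect_error(poiseuille_resistance(0.037, 5, 0), class = "coroflow_value_error")
  expect_error(poiseuille_resistance(0.037, -1, 0.1), class = "coroflow_value_error")
})

test_that("impedance magnitude matches its oracle and limiting forms", {
  expect_equal(impedance(1000, 5e-5, 0.8),
               1 / sqrt((1 / 1000)^2 + (2 * pi * 5e-5 / 0.8)^2),
               tolerance = 1e-12)
  expect_identical(impedance(1234.5, 0, 0.8), 1234.5)          # resistive limit
  expect_equal(impedance(1e12, 5e-5, 0.8), 0.8 / (2 * pi * 5e-5),
               tolerance = 1e-6)                               # capacitive limit
  expect_error(impedance(1000, 5e-5, 0), class = "coroflow_value_error")
  expect_error(impedance(-1, 0, 0.8), class = "coroflow_value_error")
})

test_that("impedance never exceeds either the resistive or capacitive bound", {
  set.seed(3)
  R <- 10^runif(200, 0, 7)
  C <- 10^runif(200, -9, -2)
  Tc <- runif(200, 0.4, 1.5)
  Z <- impedance(R, C, Tc)
  expect_true(all(Z <= pmin(R, Tc / (2 * pi * C)) + 1e-12))
})

test_that("chamber compliance matches Boyle's-law arithmetic and its limit", {
  expect_equal(chamber_compliance(760, 4.4e4, 120, 80),
               760 * 4.4e4 * (1 / 80 - 1 / 120) / (120 - 80),
               tolerance = 1e-12)
  # degenerate pulse pressure
  expect_error(chamber_compliance(760, 4.4e4, 120, 120),
               class = "coroflow_value_error")
  # Ps -> Pd limit tends to P0*V0/Pd^2
  lim <- 760 * 4.4e4 / 80^2
  expect_equal(chamber_compliance(760, 4.4e4, 80 + 1e-6, 80), lim,
               tolerance = 1e-6)
  # linear in the product P0*V0
  expect_equal(chamber_compliance(2 * 760, 4.4e4, 120, 80),
               2 * chamber_compliance(760, 4.4e4, 120, 80))
  # decreasing in both working pressures
  expect_lt(chamber_compliance(760, 4.4e4, 130, 80),
            chamber_compliance(760, 4.4e4, 120, 80))
  expect_lt(chamber_compliance(760, 4.4e4, 120, 90),
            chamber_compliance(760, 4.4e4, 120, 80))
})

test_that("segment compliance converts material area compliance to CGS", {
  # unit-conversion oracle: mm^2/mmHg * cm -> cm^5/dyn
  expect_equal(segment_compliance(0.0975, 10),
               0.0975 * 0.01 * 10 / 1333.22, tolerance = 1e-12)
  expect_identical(segment_compliance(0, 7), 0)
  expect_equal(segment_compliance(0.0975, 8), 2 * segment_compliance(0.0975, 4))
  expect_error(segment_compliance(-0.1, 5), class = "coroflow_value_error")
})

test_that("pressure conversion uses 1333.22 and round-trips exactly", {
  expect_equal(convert_pressure(100, "mmHg", "dyn_cm2"), 133322)
  expect_identical(convert_pressure(0, "mmHg", "dyn_cm2"), 0)
  x <- c(0.3, 17.2, 101.9)
  expect_equal(convert_pressure(convert_pressure(x, "mmHg", "dyn_cm2"),
                                "dyn_cm2", "mmHg"),
               x, tolerance = 1e-12)
  expect_error(convert_pressure(1, "psi", "mmHg"), class = "coroflow_value_error")
})

test_that("parameter constructors validate their physical constraints", {
  expect_error(hemo_params(viscosity_poise = 0), class = "coroflow_value_error")
  expect_error(activity_state("R", c(LAD = 1e4, LCX = 1e5, RCA = 1e5)),
               class = "coroflow_value_error")  # below the catheter range
  expect_error(activity_state("walk", c(LAD = 1e5)), class = "coroflow_value_error")
  expect_error(chamber_params(Ps_mmHg = 80, Pd_mmHg = 90),
               class = "coroflow_value_error")
  states <- default_activity_states()
  for (a in c("LAD", "LCX", "RCA")) {
    expect_gt(states$R$distal_resistance_dyn_s_cm5[[a]],
              states$E1$distal_resistance_dyn_s_cm5[[a]])
    expect_gt(states$E1$distal_resistance_dyn_s_cm5[[a]],
              states$E2$distal_resistance_dyn_s_cm5[[a]])
  }
})

test_that("the shipped default config loads and overrides apply", {
  cfg <- load_params()
  expect_s3_class(cfg$params, "hemo_params")
  expect_equal(cfg$params$total_input_flow_cc_s, 8.33)
  expect_equal(unname(cfg$chamber$inherent_resistance_dyn_s_cm5[c("LAD", "LCX", "RCA")]),
               c(1671, 1820, 591))
  expect_named(cfg$states, c("R", "E1", "E2"))

  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"hemodynamics": {"cardiac_period_s": 1.0},
               "activity_states": {"R": {"LAD": 200000, "LCX": 200000, "RCA": 200000},
                                   "E1": {"LAD": 100000, "LCX": 100000, "RCA": 100000},
                                   "E2": {"LAD": 55000, "LCX": 55000, "RCA": 55000}}}', f)
  cfg2 <- load_params(f)
  expect_equal(cfg2$params$cardiac_period_s, 1.0)
  expect_equal(unname(cfg2$states$E2$distal_resistance_dyn_s_cm5[["LAD"]]), 55000)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"activity_states": {"R": {"LAD": 60000, "LCX": 60000, "RCA": 60000},
                                   "E1": {"LAD": 100000, "LCX": 100000, "RCA": 100000},
                                   "E2": {"LAD": 200000, "LCX": 200000, "RCA": 200000}}}', bad)
  expect_error(load_params(bad), class = "coroflow_value_error")  # not monotone
})
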