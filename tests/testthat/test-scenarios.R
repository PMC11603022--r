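test_that("presets reproduce the published assay concentrations", {
  sc2 <- scenario_preset("fig2_ps_extraction")
  expect_equal(accessible_cargo(sc2$luv_a, "PS") * 2, 500)  # c_POPS total
  expect_equal(sc2$protein_nM, 250)
  expect_equal(sc2$sensor_nM, 50)
  expect_equal(sc2$regime, "extraction")

  sc3 <- scenario_preset("fig3_ps_transport")
  expect_equal(accessible_cargo(sc3$luv_a, "PS") * 2, 2000)  # 2 uM POPS
  expect_equal(sc3$luv_b$total_lipid_nM, 2e5)
  expect_equal(sc3$regime, "release")

  sc4 <- scenario_preset("fig4_pi4p_extraction")
  expect_equal(unname(sc4$luv_a$composition[c("POPC", "PI4P")]),
               c(0.99, 0.01))
  expect_equal(sc4$sensor, "SidC")
  expect_equal(sc4$sensor_nM, 100)

  sc5 <- scenario_preset("fig5_pi4p_transport")
  expect_equal(accessible_cargo(sc5$luv_a, "PI4P") * 2, 1500)
  expect_equal(sc5$regime, "release")

  sc7 <- scenario_preset("fig7_pm_like")
  expect_equal(sc7$preincubation$minutes, 10)
  expect_equal(unname(sc7$preincubation$luv$composition["POPS"]), 0.2)
})

test_that("every preset's regime flag matches its cargo/protein ratio", {
  for (nm in setdiff(scenario_presets(), "fig6_binding")) {
    sc <- scenario_preset(nm)
    ratio <- accessible_cargo(sc$luv_a, sc$sensed_cargo) / sc$protein_nM
    if (sc$regime == "extraction") expect_lte(ratio, 1.5)
    else expect_gt(ratio, 1.5)
  }
})

test_that("unknown presets and malformed scenarios are rejected", {
  expect_error(scenario_preset("not_a_preset"), "valid presets")
  luv <- luv_population(c(POPC = 1), 5e4)
  expect_error(assay_scenario(luv, protein_nM = 250, sensor = "C2Lact",
                              sensor_nM = 50, t_grid = c(1, 2)),
               "start at 0")
  expect_error(assay_scenario(luv, protein_nM = -1, sensor = "C2Lact",
                              sensor_nM = 50), "nonnegative")
})

test_that("scenarios survive a YAML round trip", {
  sc <- scenario_preset("fig3_ps_transport",
                        luv_b_composition = c(POPC = 95, POPG = 5))
  path <- tempfile(fileext = ".yml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$luv_a$composition, sc$luv_a$composition)
  expect_equal(back$luv_b$composition, sc$luv_b$composition)
  expect_equal(back$protein_nM, sc$protein_nM)
  expect_equal(back$sensor_nM, sc$sensor_nM)
  expect_equal(back$t_grid, sc$t_grid)
  expect_equal(back$regime, sc$regime)
  unlink(path)
})
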