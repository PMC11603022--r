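test_that("vesicle geometry gives the expected lipid and dye counts", {
  luv <- luv_population(c(POPC = 0.99, PI4P = 0.01), total_lipid_nM = 5e4)
  # sphere areas of both leaflets at 0.65 nm^2 per lipid
  expect_equal(luv$lipids_per_vesicle,
               4 * pi * (25^2 + 21^2) / 0.65, tolerance = 1e-12)
  expect_equal(round(luv$lipids_per_vesicle), 20609)
  expect_equal(round(luv$outer_leaflet_lipids), 12083)
  expect_equal(round(luv$inner_leaflet_lipids), 8526)
  expect_equal(luv$vesicle_nM, 5e4 / luv$lipids_per_vesicle)
  expect_equal(luv$vesicle_nM, 2.43, tolerance = 0.005)
  expect_equal(luv$mean_dyes_per_vesicle, 2.06, tolerance = 0.005)
  # product invariant
  expect_equal(luv$vesicle_nM * luv$lipids_per_vesicle, 5e4,
               tolerance = 1e-9)
})

test_that("mol percents and mol fractions are both accepted, bad input is not", {
  a <- luv_population(c(POPC = 99, PI4P = 1), 5e4)
  b <- luv_population(c(POPC = 0.99, PI4P = 0.01), 5e4)
  expect_equal(a$composition, b$composition)
  expect_error(luv_population(c(POPC = 0.7, POPS = 0.2), 5e4), "sum to 1")
  expect_error(luv_population(c(POPC = 1), -5), "positive")
  expect_error(luv_population(c(POPC = 1), 5e4, diameter_nm = 7), "diameter")
})

test_that("accessible cargo follows fraction x mol fraction x total lipid", {
  luv <- luv_population(c(POPC = 0.94, phPG = 0.05, POPS = 0.01), 5e4)
  # 1 mol% PS of 50 uM with the outer-leaflet half accessible = 250 nM,
  # stoichiometric with the 250 nM transporter of the extraction assay
  expect_equal(accessible_cargo(luv, "PS"), 250)
  expect_equal(accessible_cargo(luv, "PI4P"), 0)
  luv5 <- luv_population(c(POPC = 0.97, PI4P = 0.03), 5e4)
  expect_equal(accessible_cargo(luv5, "PI4P"), 750)
  # geometric outer-leaflet alternative
  luv_g <- luv_population(c(POPC = 0.99, POPS = 0.01), 5e4,
                          accessible_fraction = "geometric")
  expect_equal(luv_g$accessible_fraction, 0.5863, tolerance = 1e-3)
})

test_that("non-extractable diphytanoyl species are counted for charge only", {
  luv <- luv_population(c(POPC = 0.8, phPS = 0.2), 5e4)
  expect_equal(accessible_cargo(luv, "PS"), 0.2 * 0.5 * 5e4)
  expect_equal(accessible_cargo(luv, "PS", extractable_only = TRUE), 0)
  info <- lipid_info(c("phPS", "POPS", "PIP2", "PI4P"))
  expect_false(info$extractable[info$name == "phPS"])
  expect_true(info$extractable[info$name == "POPS"])
  expect_equal(info$headgroup_charge, c(-1, -1, -4, -1))
})

test_that("scaling total lipid scales vesicles but not geometry", {
  luv1 <- luv_population(c(POPC = 1), 5e4)
  luv2 <- luv_population(c(POPC = 1), 1e5)
  expect_equal(luv2$vesicle_nM, 2 * luv1$vesicle_nM)
  expect_equal(luv2$lipids_per_vesicle, luv1$lipids_per_vesicle)
})

test_that("unknown lipids warn and act as neutral filler", {
  expect_warning(info <- lipid_info(c("POPC", "mystery_lipid")), "unknown")
  expect_equal(info$headgroup_charge[2], 0)
})
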