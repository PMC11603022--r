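test_that("network enumerates load states and membrane copies", {
  sc <- scenario_preset("fig2_ps_extraction",
                        luv_b_composition = c(POPC = 0.99, PI4P = 0.01))
  net <- build_network(sc)
  # PS and PI4P both circulate: 3 load states x (solution + 2 membranes)
  p_states <- grep("^P_", net$species, value = TRUE)
  expect_setequal(p_states, as.vector(outer(
    c("none", "PS", "PI4P"), c("sol", "A", "B"),
    function(l, x) paste("P", l, x, sep = "_"))))
  expect_true(any(grepl("^exchange_fwd", vapply(net$reactions, `[[`, "",
                                                "name"))))
})

test_that("a cargo-free scenario yields a transporter-only network", {
  sc <- assay_scenario(luv_population(c(POPC = 1), 5e4), protein_nM = 250,
                       sensor = "C2Lact", sensor_nM = 50, t_grid = 0:5)
  net <- build_network(sc)
  expect_setequal(grep("^P_", net$species, value = TRUE),
                  c("P_none_sol", "P_none_A"))
  expect_false(any(grepl("extract", vapply(net$reactions, `[[`, "", "name"))))
})

test_that("non-extractable phPS adds charge but no reactions", {
  sc <- assay_scenario(luv_population(c(POPC = 0.8, phPS = 0.2), 5e4),
                       protein_nM = 250, sensor = "C2Lact", sensor_nM = 50,
                       t_grid = 0:10, regime = "release")
  net <- build_network(sc)
  expect_false(any(grepl("extract", vapply(net$reactions, `[[`, "", "name"))))
  expect_gt(net$membranes$A$ads_mult[["none"]], 1)  # charge + packing
  # and the readout stays at its baseline: displacement alone is silent
  r <- readout_from_trajectory(simulate_kinetics(net))
  expect_lt(max(abs(r$readout - r$readout[1])), 1e-6)
})

test_that("cargo and transporter are conserved to 1e-8 on stiff trajectories", {
  for (nm in c("fig2_ps_extraction", "fig3_ps_transport",
               "fig4_pi4p_extraction")) {
    traj <- simulate_kinetics(build_network(scenario_preset(nm)),
                              t_grid = seq(0, 20, 0.5))
    expect_lt(max(conservation_error(traj)), 1e-8)
    expect_true(all(as.matrix(traj[, -1]) > -1e-9))
  }
})

test_that("without transporter nothing moves", {
  sc <- scenario_preset("fig2_ps_extraction")
  sc$protein_nM <- 0
  net <- build_network(sc)
  traj <- simulate_kinetics(net, t_grid = 0:10)
  expect_lt(max(abs(traj$PS_A - traj$PS_A[1])), 1e-9)
})

test_that("PS extraction is stoichiometric and near-complete within a minute", {
  traj <- simulate_kinetics(build_network(scenario_preset("fig2_ps_extraction")),
                            t_grid = 0:10)
  occ <- protein_occupancy(traj)
  expect_gte(occ$load_PS[occ$time_min == 1], 0.9)
  r <- readout_from_trajectory(traj)
  expect_lt(r$readout[r$time_min == 1] / r$readout[1], 0.25)
})

test_that("more extraction-prone transporter never extracts less", {
  sc <- scenario_preset("fig2_ps_extraction")
  extracted <- sapply(c(1e4, 4e4, 1.6e5), function(k) {
    p <- kinetic_params(k_ext = c(PS = k, PI4P = 5500))
    traj <- simulate_kinetics(build_network(sc, p), t_grid = 0:10)
    traj$PS_A[1] - traj$PS_A  # extracted by each time
  })
  for (j in seq_len(ncol(extracted) - 1))
    expect_true(all(extracted[, j + 1] - extracted[, j] > -1e-8))
})

test_that("a competing pocket ligand in the acceptor suppresses PS delivery", {
  for (scale in c(0.7, 1, 1.4)) {
    p <- kinetic_params()
    p$k_rel["PS"] <- p$k_rel[["PS"]] * scale
    late_ps_on_b <- function(b_comp) {
      sc <- scenario_preset("fig3_ps_transport", luv_b_composition = b_comp)
      traj <- simulate_kinetics(build_network(sc, p), t_grid = c(0, 30, 60))
      traj$PS_B[traj$time_min == 60]
    }
    expect_lt(late_ps_on_b(c(POPC = 0.95, PI4P = 0.05)),
              late_ps_on_b(c(POPC = 1)))
  }
})

test_that("symmetric membranes split the cargo equally at steady state", {
  # all composition-asymmetric modifiers off, K_comp = 1
  p <- kinetic_params(K_comp = 1, charge_coeff = 0, ext_charge_coeff = 0,
                      ads_charge_coeff = 0, ads_packing_coeff = 0)
  luv_a <- luv_population(c(POPC = 0.98, POPS = 0.01, PI4P = 0.01), 5e4)
  luv_b <- luv_population(c(POPC = 1), 5e4, did_per_lipid = 0)
  sc <- assay_scenario(luv_a, luv_b, protein_nM = 250, sensor = "C2Lact",
                       sensor_nM = 0, t_grid = c(0, 2000), regime = "release")
  traj <- simulate_kinetics(build_network(sc, p))
  final <- traj[nrow(traj), ]
  expect_equal(final$PS_A, final$PS_B, tolerance = 1e-3)
  expect_equal(final$PI4P_A, final$PI4P_B, tolerance = 1e-3)
})

test_that("a stochastic realization reproduces the ODE mean", {
  sc <- assay_scenario(luv_population(c(POPC = 0.99, POPS = 0.01), 5e4),
                       protein_nM = 250, sensor = "C2Lact", sensor_nM = 0,
                       t_grid = c(0, 0.5, 1, 2))
  net <- build_network(sc)
  ode <- simulate_kinetics(net)
  set.seed(99)
  runs <- replicate(30, simulate_gillespie(net, omega = 0.2)$PS_A[4])
  mc_se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - ode$PS_A[4]), 4 * mc_se + 1)
  expect_error(simulate_gillespie(build_network(
    scenario_preset("fig2_ps_extraction"))), "sensor_nM = 0")
})

test_that("preincubation preloads the transporter before the assay", {
  sc <- scenario_preset("fig7_pm_like")
  traj <- simulate_kinetics(build_network(sc))
  occ <- protein_occupancy(traj)
  # at t = 0 the transporter arrives already loaded with PS from LUVs B
  expect_gt(occ$load_PS[1], 0.8)
  expect_lt(max(conservation_error(traj)), 1e-8)
})

test_that("charged membranes bind the empty transporter best, loaded least", {
  p <- kinetic_params()
  occ_on_a <- function(comp, pre = NULL) {
    sc <- scenario_preset("fig6_binding", luv_a_composition = comp,
                          luv_b_composition = pre)
    traj <- simulate_kinetics(build_network(sc, p))
    r <- readout_from_trajectory(traj)  # adsorbed fraction on LUVs A
    r$readout[nrow(r)]
  }
  neutral <- occ_on_a(c(POPC = 1))
  charged <- occ_on_a(c(POPC = 0.8, phPG = 0.2))
  loaded <- occ_on_a(c(POPC = 0.8, phPG = 0.2),
                     pre = c(DOPC = 0.8, POPS = 0.2))
  expect_gt(charged, neutral)
  expect_gt(charged, loaded)
})

test_that("integration refuses malformed grids", {
  net <- build_network(scenario_preset("fig2_ps_extraction"))
  expect_error(simulate_kinetics(net, t_grid = c(1, 2)), "start at 0")
  expect_error(simulate_kinetics(net, t_grid = c(0, 0, 1)), "increasing")
})

test_that("trajectories export to tidy long-format CSV", {
  traj <- simulate_kinetics(build_network(scenario_preset("fig2_ps_extraction")),
                            t_grid = 0:3)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  long <- read.csv(path)
  expect_setequal(names(long),
                  c("time_min", "compartment", "species", "amount_nM"))
  expect_equal(nrow(long), 4 * (ncol(traj) - 1))
  ps_a <- long[long$species == "PS" & long$compartment == "membrane_A", ]
  expect_equal(ps_a$amount_nM[order(ps_a$time_min)], traj$PS_A,
               tolerance = 1e-9)
  unlink(path)
})
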