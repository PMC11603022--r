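test_that("traces are bit-reproducible for a given seed", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3)
  ens <- uniform_luv_ensemble(10)
  a <- simulate_photon_trace(ens, opt, 0.5, seed = 7)
  b <- simulate_photon_trace(ens, opt, 0.5, seed = 7)
  c <- simulate_photon_trace(ens, opt, 0.5, seed = 8)
  expect_identical(a$g, b$g)
  expect_identical(a$r, b$r)
  expect_false(identical(a$r, c$r))
})

test_that("dark particles give an all-zero trace", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3)
  ens <- uniform_luv_ensemble(10, dyes = 0, greens = 0)
  tr <- simulate_photon_trace(ens, opt, 0.2, seed = 1)
  expect_true(all(tr$g == 0) && all(tr$r == 0))
})

test_that("an immobile particle at the focus center counts q x dt per bin", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3, brightness_r = 5e4)
  ens <- particle_ensemble("bead", d_um2s = 0, n_green = 0, n_red = 1)
  tr <- simulate_photon_trace(ens, opt, 2, seed = 2,
                              positions = matrix(0, 1, 3))
  expected <- 5e4 * 1e-4
  n <- length(tr$r)
  expect_equal(mean(tr$r), expected,
               tolerance = 4 * sqrt(expected / n) / expected)
})

test_that("mean count rate matches the analytic profile integral", {
  # <rate> = q x (volume average of the Gaussian profile over the box)
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3, brightness_r = 1e5)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  i1 <- function(s, h) s * sqrt(pi / 2) * erf(h * sqrt(2) / s)
  h <- opt$box_um / 2
  w_mean <- i1(opt$w0_um, h)^2 * i1(opt$kappa * opt$w0_um, h) / opt$box_um^3
  n <- 40
  ens <- particle_ensemble(rep("p", n), rep(20, n), rep(0, n), rep(1, n))
  tr <- simulate_photon_trace(ens, opt, 60, seed = 5)
  expected <- n * 1e5 * w_mean * opt$bin_width_s
  expect_equal(mean(tr$r), expected, tolerance = 0.02)
})

test_that("kinetic states realize into consistent particle ensembles", {
  expect_equal(molecules_in_box(2.43, 3), 39.5, tolerance = 0.005)
  sc <- scenario_preset("fig2_ps_extraction")
  traj <- simulate_kinetics(build_network(sc), t_grid = 0:3)
  opt <- optics_config(box_um = 6)
  ens <- ensemble_from_state(traj, -1, opt, seed = 3, dilution = 20,
                             luv_dilution = 2)
  expect_s3_class(ens, "particle_ensemble")
  # bound fraction of the realized sensors matches the isotherm in
  # expectation (binomial check over seeds)
  net <- attr(traj, "network")
  f_true <- sensor_partition(net$state0, net)$bound_on[["A"]] / 50
  f_hat <- sapply(1:10, function(s) {
    e <- ensemble_from_state(traj, -1, opt, seed = s, dilution = 20,
                             luv_dilution = 2)
    luvs <- e$species == "luv_a"
    sum(e$n_green[luvs]) / sum(e$n_green)
  })
  n_sens <- molecules_in_box(50 / 20, 6)
  expect_lt(abs(mean(f_hat) - f_true),
            3 * sqrt(f_true * (1 - f_true) / (10 * n_sens)))
  # impossible box: too few vesicles
  expect_error(ensemble_from_state(traj, -1, optics_config(box_um = 3),
                                   seed = 1, dilution = 1000),
               "fewer than 10")
})

test_that("a vesicle-free state realizes as free sensors only", {
  sc <- assay_scenario(luv_population(c(POPC = 1), 1e-9, did_per_lipid = 0),
                       protein_nM = 0, sensor = "C2Lact", sensor_nM = 50,
                       t_grid = 0:2, regime = "extraction")
  sc$luv_a$vesicle_nM <- 0
  traj <- simulate_kinetics(build_network(sc))
  ens <- ensemble_from_state(traj, -1, optics_config(box_um = 3), seed = 1)
  expect_true(all(ens$species == "sensor"))
  expect_true(all(ens$n_red == 0))
})

test_that("trace CSV round trip preserves counts and metadata", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3)
  tr <- simulate_photon_trace(uniform_luv_ensemble(10, greens = 1), opt,
                              0.2, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_identical(back$g, tr$g)
  expect_identical(back$r, tr$r)
  expect_equal(back$bin_width_s, tr$bin_width_s)
  unlink(path)
})
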