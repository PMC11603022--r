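test_that("a constant trace has zero correlation everywhere", {
  tr <- photon_trace(rep(3L, 5000), rep(2L, 5000), 1e-4)
  cd <- correlate_direct(tr, c(1, 2, 5, 10))
  expect_true(all(abs(as.matrix(cd[, -1])) < 1e-12))
  cm <- correlate_multitau(tr)
  expect_true(all(abs(cm$GR) < 1e-12))
})

test_that("the alternating trace matches the hand-computed lag-1 value", {
  a <- 4; b <- 1
  x <- rep(c(a, b), 3000)
  tr <- photon_trace(x, x, 1e-4)
  cd <- correlate_direct(tr, 1:2)
  # delta I alternates +-(a-b)/2 around the mean (a+b)/2, so at lag 1
  # G = -((a-b)/2)^2 / ((a+b)/2)^2; at lag 2 the sign flips back
  expect_equal(cd$GG[1], -((a - b) / 2)^2 / ((a + b) / 2)^2,
               tolerance = 1e-3)
  expect_equal(cd$GG[2], +((a - b) / 2)^2 / ((a + b) / 2)^2,
               tolerance = 1e-3)
})

test_that("independent Poisson bins decorrelate", {
  set.seed(42)
  tr <- photon_trace(rpois(2e4, 2), rpois(2e4, 3), 1e-4)
  cd <- correlate_direct(tr, c(1, 5, 20))
  se <- 1 / sqrt(2e4 * 2 * 3)  # scale of the cross term noise
  expect_true(all(abs(cd$Gcc) < 3 * se))
  expect_true(all(abs(cd$GG) < 3 / (2 * sqrt(2e4))))
})

test_that("multi-tau equals the direct estimator exactly on its base cascade", {
  set.seed(7)
  x <- rpois(4000, 5) + rep(c(0, 2), each = 4, length.out = 4000)
  tr <- photon_trace(x, rev(x), 1e-4)
  cm <- correlate_multitau(tr, m = 16)
  cd <- correlate_direct(tr, 1:16)
  expect_equal(cm$GG[1:16], cd$GG, tolerance = 1e-12)
  expect_equal(cm$Gcc[1:16], cd$Gcc, tolerance = 1e-12)
})

test_that("progressive binning tracks a smooth deterministic correlation", {
  # noise-free sinusoidal intensity: the correlogram is a cosine; coarse
  # cascades must follow it closely where it is resolved
  t <- seq_len(2^15)
  x <- 100 * (2 + sin(2 * pi * t / 4096))
  tr <- photon_trace(as.integer(round(x)), as.integer(round(x)), 1e-5)
  cm <- correlate_multitau(tr, m = 16)
  lag_bins <- round(cm$lag_s / 1e-5)
  # the progressive binning is a low-pass: it is faithful while the
  # cascade bin stays well below the signal timescale (here, bins up to
  # period/16; the deepest cascades average the oscillation away)
  keep <- lag_bins < length(x) / 2 & lag_bins <= 3500
  cm <- cm[keep, ]
  cd <- correlate_direct(tr, lag_bins[keep])
  sel <- abs(cd$GG) > 0.25 * max(cd$GG)
  expect_lt(max(abs(cm$GG[sel] - cd$GG[sel]) / abs(cd$GG[sel])), 0.03)
})

test_that("cross-correlation is symmetric under channel swap on stationary traces", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3)
  ens <- uniform_luv_ensemble(15, dyes = 2, greens = 1)
  tr <- simulate_photon_trace(ens, opt, 10, seed = 9)
  cm <- correlate_multitau(tr)
  early <- cm$lag_s <= 0.005
  expect_equal(cm$Gcc[early], cm$Gcc_rev[early], tolerance = 0.15)
  expect_gt(cor(cm$Gcc, cm$Gcc_rev), 0.98)
})

test_that("degenerate traces are rejected with a clear message", {
  tr <- photon_trace(rep(0L, 5000), rep(1L, 5000), 1e-4)
  expect_error(correlate_direct(tr, 1), "zero-mean")
  expect_warning(cm <- correlate_multitau(tr), "skipped")
  expect_true(all(is.na(cm$GG)))
  expect_false(anyNA(cm$GR))
  tr2 <- photon_trace(rep(1L, 50), rep(1L, 50), 1e-4)
  expect_error(correlate_multitau(tr2), "too short")
  expect_error(correlate_direct(tr2, 30), "half the trace")
})

test_that("uncorrelated channels give a flat cross-correlation", {
  opt <- optics_config(bin_width_s = 1e-4, box_um = 3)
  n <- 20
  # half the particles green-only, half red-only: no co-diffusion
  ens <- particle_ensemble(rep(c("g", "r"), each = n),
                          rep(stokes_einstein_D(25), 2 * n),
                          n_green = rep(c(1, 0), each = n),
                          n_red = rep(c(0, 1), each = n))
  tr <- simulate_photon_trace(ens, opt, 20, seed = 12)
  cm <- correlate_multitau(tr, n_segments = 8)
  z <- abs(cm$Gcc) / cm$se_Gcc
  expect_lt(mean(abs(cm$Gcc)), 3 * mean(cm$se_Gcc))
  expect_gt(mean(cm$GR[1:8]), 10 * mean(cm$se_GR[1:8]))  # autocorr is real
})
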