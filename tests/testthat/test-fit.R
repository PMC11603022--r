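make_model_curve <- function(G0 = 0.1, tauD = 1e-3, kappa = 5,
                             noise_sd = 0, seed = 1) {
  lags <- 1e-5 * 2^(seq(0, 14, 0.25))
  g <- diffusion_model(lags, G0, tauD, kappa)
  if (noise_sd > 0) {
    set.seed(seed)
    g <- g + rnorm(length(g), sd = noise_sd * G0)
  }
  out <- data.frame(lag_s = lags, GG = g, GR = g, Gcc = g)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

test_that("a noise-free model curve is recovered exactly", {
  fit <- fit_diffusion(make_model_curve(), "GR", kappa = 5)
  expect_equal(coef(fit)[["G0"]], 0.1, tolerance = 1e-9)
  expect_equal(coef(fit)[["tauD"]], 1e-3, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("the model obeys the half-amplitude identity at tau = tauD", {
  for (kappa in c(3, 5, 8)) {
    expect_equal(diffusion_model(1e-3, 0.2, 1e-3, kappa),
                 0.2 / (2 * sqrt(1 + 1 / kappa^2)), tolerance = 1e-12)
  }
})

test_that("amplitude recovery stays within 5% under 5% noise", {
  errs <- vapply(1:20, function(s) {
    fit <- fit_diffusion(make_model_curve(noise_sd = 0.05, seed = s), "GR")
    abs(coef(fit)[["G0"]] - 0.1) / 0.1
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the two-component model separates fast and slow species", {
  lags <- 1e-5 * 2^(seq(0, 14, 0.25))
  shape <- function(tauD) diffusion_model(lags, 1, tauD, 5)
  g <- 0.2 * (0.4 * shape(2e-4) + 0.6 * shape(5e-3))
  cur <- data.frame(lag_s = lags, GG = g, GR = g, Gcc = g)
  class(cur) <- c("correlation_curve", "data.frame")
  fit <- fit_diffusion(cur, "GG", components = 2,
                       start = list(tauD1 = 1e-4, tauD2 = 1e-2))
  cf <- coef(fit)
  expect_equal(cf[["G0"]], 0.2, tolerance = 1e-3)
  tds <- sort(c(cf[["tauD1"]], cf[["tauD2"]]))
  expect_equal(tds, c(2e-4, 5e-3), tolerance = 1e-2)
})

test_that("predict and residuals methods are consistent", {
  cur <- make_model_curve(noise_sd = 0.02)
  fit <- fit_diffusion(cur, "GR")
  expect_equal(as.numeric(predict(fit) + residuals(fit)), cur$GR,
               tolerance = 1e-12)
  expect_equal(predict(fit, tau = 1e-3),
               diffusion_model(1e-3, coef(fit)[["G0"]], coef(fit)[["tauD"]], 5))
})

test_that("readout ratio demands a red amplitude", {
  lags <- 1e-5 * 2^(seq(0, 14, 0.5))
  cur <- data.frame(lag_s = lags, GG = rep(0, length(lags)),
                    GR = rep(0, length(lags)), Gcc = rep(0, length(lags)))
  class(cur) <- c("correlation_curve", "data.frame")
  expect_error(readout_ratio(cur), "no red species")
})
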