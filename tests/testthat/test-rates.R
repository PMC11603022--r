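test_that("extraction rate reproduces its closed-form cases", {
  s <- readout_series(c(0, 1, 3), c(1, 0, 0))
  expect_equal(extraction_rate(s, 250, 250, t = 1)$value, 1)
  # complete drop at time t gives c_acc / (c_prot * t) exactly
  expect_equal(extraction_rate(s, 750, 250, t = 3, cargo = "PI4P")$value, 1)
  s2 <- readout_series(c(0, 3), c(1, 0.5))
  expect_equal(extraction_rate(s2, 250, 250, t = 3)$value, 1 / 6,
               tolerance = 1e-12)
  # no drop -> zero
  s3 <- readout_series(c(0, 1), c(0.8, 0.8))
  expect_equal(extraction_rate(s3, 250, 250, t = 1)$value, 0)
})

test_that("transport rate reproduces its closed-form cases", {
  s <- readout_series(c(0, 1, 10), c(0.85, 0.8, 0.4))
  expect_equal(transport_rate(s, 1000, 250, t1 = 1, t2 = 10)$value,
               3 * 0.5 / 9, tolerance = 1e-12)
  s2 <- readout_series(c(0, 6, 16), c(1, 1, 0.5))
  expect_equal(transport_rate(s2, 750, 250, cargo = "PI4P")$value,
               2 * 0.5 / 10, tolerance = 1e-12)
  s3 <- readout_series(c(0, 1, 10), c(0.9, 0.7, 0.7))
  expect_equal(transport_rate(s3, 1000, 250)$value, 0)
})

test_that("the overall drop estimator reproduces its closed-form cases", {
  s <- readout_series(c(0, 10), c(1, 0.6))
  expect_equal(pi4p_drop(s, 250, 250)$value, 0.4, tolerance = 1e-12)
  expect_equal(pi4p_drop(readout_series(c(0, 10), c(1, 1)), 250, 250)$value, 0)
  # full drop reaches the stoichiometric ceiling c_acc / c_prot
  expect_equal(pi4p_drop(readout_series(c(0, 10), c(1, 0)), 750, 250)$value, 3)
})

test_that("all three estimators are invariant to rescaling the readout", {
  times <- c(0, 1, 3, 6, 10, 16)
  vals <- c(0.9, 0.7, 0.55, 0.45, 0.35, 0.3)
  for (k in c(0.01, 1, 37)) {
    a <- readout_series(times, vals)
    b <- readout_series(times, k * vals)
    expect_equal(extraction_rate(a, 250, 250)$value,
                 extraction_rate(b, 250, 250)$value, tolerance = 1e-12)
    expect_equal(transport_rate(a, 1000, 250)$value,
                 transport_rate(b, 1000, 250)$value, tolerance = 1e-12)
    expect_equal(pi4p_drop(a, 750, 250)$value,
                 pi4p_drop(b, 750, 250)$value, tolerance = 1e-12)
  }
})

test_that("estimators refuse inputs outside their domain", {
  s <- readout_series(c(0, 1, 10), c(0.9, 0.8, 0.5))
  expect_error(extraction_rate(s, 250, 250, t = 2), "interpolation")
  expect_error(extraction_rate(readout_series(c(0, 1), c(0, 0)), 250, 250,
                               t = 1), "baseline")
  expect_error(transport_rate(s, 200, 250), "release regime")
  expect_error(transport_rate(s, 1000, 250, t1 = 5, t2 = 2), "exceed")
})

test_that("outlier screening excludes exactly the discordant point", {
  vals <- c(rep(1, 9), 5)
  # full-sample SD = 1.2649, so the cut sits at 1.4 +- 1.897
  expect_equal(sd(vals), 1.2649, tolerance = 1e-4)
  st <- replicate_stats(vals)
  expect_equal(st$excluded, 10L)
  expect_equal(st$mean, 1)
  expect_equal(st$sem, 0)
})

test_that("screening keeps symmetric mild outliers and equal samples", {
  vals <- c(1, 1, 1, 1.4, 0.6)  # both deviations stay within 1.5 SD
  st <- replicate_stats(vals)
  expect_equal(st$kept, 1:5)
  st2 <- replicate_stats(rep(2.5, 5))
  expect_equal(st2$mean, 2.5)
  expect_equal(st2$sem, 0)
  expect_error(replicate_stats(c(1, 2)), "at least 3")
})

test_that("the pooled t-test matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- two_sample_ttest(a, b)
  oracle <- ttest_textbook(a, b)
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878641, tolerance = 1e-6)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
})

test_that("t-test edge cases behave as documented", {
  expect_equal(two_sample_ttest(c(1, 1, 1), c(1, 1))$p, 1)
  deg <- two_sample_ttest(c(1, 1), c(2, 2))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  # widely separated samples are overwhelmingly significant
  set.seed(3)
  a <- rnorm(5, 0, 1); b <- rnorm(5, 30, 1)
  expect_lt(two_sample_ttest(a, b)$p, 1e-4)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})
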