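test_that("the Hurwitz zeta shortcut matches direct summation", {
  for (s in c(1.2, 1.5, 2.5)) {
    for (a in c(1, 7, 100)) {
      direct <- sum((a + 0:2e6) ^ (-s)) # truncated direct sum as oracle
      tail_correction <- (a + 2e6 + 1) ^ (1 - s) / (s - 1)
      expect_equal(critsig:::hurwitz_zeta(s, a), direct + tail_correction,
                   tolerance = 1e-6)
    }
  }
})

test_that("the discrete MLE recovers a known exponent to within 0.02", {
  x <- sample_power_law(1e6, 1.5, xmin = 1, xmax = 1e6, seed = 7)
  fit <- fit_power_law(x, xmin = 1, n_boot = 0)
  expect_equal(fit$exponent, 1.5, tolerance = 0.02)
})

test_that("sampled data follow the requested truncated support", {
  x <- sample_power_law(1e4, 2, xmin = 3, xmax = 50, seed = 2)
  expect_true(all(x >= 3 & x <= 50))
  expect_true(all(x == round(x)))
})

test_that("geometric samples are rejected as a power law", {
  set.seed(5)
  geo <- rgeom(1e5, 0.2) + 1
  fit <- fit_power_law(geo, xmin = 1, n_boot = 60)
  expect_lt(fit$boot_p, 0.1)
  # the likelihood ratio must favour the exponential alternative
  expect_lt(fit$comparisons$loglik_ratio[
    fit$comparisons$alternative == "exponential"], 0)
})

test_that("power-law samples are not rejected and beat both alternatives", {
  x <- sample_power_law(2e4, 1.6, xmin = 1, xmax = 1e5, seed = 11)
  fit <- fit_power_law(x, xmin = 1, n_boot = 60)
  expect_gte(fit$boot_p, 0.1)
  expect_true(all(fit$comparisons$loglik_ratio > 0))
})

test_that("degenerate or insufficient samples raise typed errors", {
  expect_error(fit_power_law(rep(7, 500)),
               class = "critsig_insufficient_data")
  expect_error(fit_power_law(c(1, 2, 3, 4, 5)),
               class = "critsig_insufficient_data")
})

test_that("the exponent is stable under subsampling half the data", {
  x <- sample_power_law(4e4, 1.5, xmin = 1, xmax = 1e5, seed = 13)
  full <- fit_power_law(x, xmin = 1, n_boot = 0)
  set.seed(1)
  half <- fit_power_law(sample(x, length(x) / 2), xmin = 1, n_boot = 0)
  expect_equal(full$exponent, half$exponent, tolerance = 0.05)
})

test_that("KS-selected xmin lands low for clean power-law data", {
  x <- sample_power_law(5e4, 1.8, xmin = 1, xmax = 1e5, seed = 17)
  fit <- fit_power_law(x, n_boot = 0)
  expect_lt(fit$xmin, 10)
  expect_equal(fit$exponent, 1.8, tolerance = 0.05)
})
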