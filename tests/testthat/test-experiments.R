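test_that("classify_system is total, deterministic, and matches the chart", {
  # the three worked cases
  expect_equal(classify_system(FALSE, TRUE, TRUE)$label, "not_critical")
  expect_equal(classify_system(TRUE, FALSE, TRUE)$label,
               "low_dimensional_driven")
  expect_equal(classify_system(TRUE, TRUE, FALSE)$label, "emergent_critical")
  # all eight gate combinations resolve, first gate dominating
  for (b in c(TRUE, FALSE)) for (n in c(TRUE, FALSE))
    for (k in c(TRUE, FALSE)) {
      lab <- classify_system(b, n, k)$label
      expect_true(lab %in% c("not_critical", "low_dimensional_driven",
                             "emergent_critical", "novel"))
      if (!b) expect_equal(lab, "not_critical")
    }
  expect_equal(classify_system(TRUE, TRUE, TRUE)$label, "novel")
})

test_that("post-stimulus activity is statistically non-increasing in g", {
  cfg <- brunel_config(n_neurons = 500)
  res <- suppressWarnings(
    sweep_decay(cfg, g_grid = c(1.5, 3, 4.5, 6), n_trials = 8, seed = 3))
  expect_true(all(diff(res$firing_rate) < 0.02))
  expect_gt(res$firing_rate[1], 5 * res$firing_rate[4])
})

test_that("identical seeds give an attribution ratio of exactly 1 for
           matched disconnected models", {
  cfg <- brunel_config(n_neurons = 200, connection_density = 0)
  att <- entropy_attribution(cfg, g_grid = c(3), n_driven = 200,
                             n_trials = 6, seed = 2)
  expect_equal(att$percent, 100, tolerance = 1e-10)
})

test_that("the exponential asymptote fit recovers a known limit", {
  sizes <- c(250, 500, 1000, 1500, 2000)
  peaks <- tibble::tibble(size = sizes,
                          peak_g = 2.95 - 1.2 * exp(-sizes / 600))
  fit <- suppressWarnings(critsig:::try_asymptote(peaks))
  expect_equal(fit$asymptote, 2.95, tolerance = 0.01)
  expect_true(fit$ci_lo <= 2.95 && 2.95 <= fit$ci_hi)
})

test_that("a noiseless mi_sweep equals the p_spont = 0 noise sweep", {
  cfg <- brunel_config(n_neurons = 300)
  a <- sweep_mi(cfg, g_grid = c(2.5, 3.5), n_models = 1, n_trials = 5,
                seed = 4)
  b <- sweep_mi(cfg, g_grid = c(2.5, 3.5), n_models = 1, n_trials = 5,
                noise = list(p_spont = 0), seed = 4)
  expect_equal(a$curves$mi_mean, b$curves$mi_mean)
})

test_that("MI never exceeds the 3-bit input entropy anywhere on a sweep", {
  cfg <- brunel_config(n_neurons = 300)
  res <- sweep_mi(cfg, g_grid = c(2, 3, 4), n_models = 2, n_trials = 6,
                  seed = 5)
  expect_true(all(res$curves$mi_mean <= 3 + 1e-9))
  expect_true(all(res$curves$mi_mean >= 0))
})
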