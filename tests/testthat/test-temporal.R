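test_that("the two-point standard-deviation ratio gives H near 0.51", {
  expect_equal(hurst_two_point(70.26, 202.13, 8), 0.51, tolerance = 0.005)
})

test_that("a linear ramp has H = 1 and white noise a flat STD curve", {
  # within-window STD of a ramp is sqrt((L^2 - 1) / 12), linear in L up to
  # a small discrete correction at the shortest windows
  ramp <- hurst_exponent(seq_len(2^14))
  expect_equal(ramp$H, 1, tolerance = 0.02)
  set.seed(3)
  noise <- hurst_exponent(rnorm(2^16))
  expect_equal(noise$H, 0, tolerance = 0.02)
})

test_that("a fair walk of 2^20 steps has H in [0.45, 0.55]", {
  w <- coin_flip_walk(2^20, reflect = FALSE, seed = 12)
  h <- hurst_exponent(w)
  expect_gte(h$H, 0.45)
  expect_lte(h$H, 0.55)
})

test_that("persistent walks are super-diffusive, antipersistent sub-diffusive", {
  # a Markov persistent walk is diffusive beyond its persistence length
  # (a few steps), so the scaling must be probed at crossover windows
  lad <- 2 ^ (1:5)
  hp <- hurst_exponent(persistent_walk(2^18, persist = 0.7, seed = 4),
                       window_lengths = lad)
  ha <- hurst_exponent(persistent_walk(2^18, persist = 0.3, seed = 4),
                       window_lengths = lad)
  expect_gt(hp$H, 0.5)
  expect_lt(ha$H, 0.45)
})

test_that("the windowed-STD ladder behaves and validates its input", {
  w <- coin_flip_walk(2^15, reflect = FALSE, seed = 5)
  h <- hurst_exponent(w)
  expect_equal(h$table$window_length, 2 ^ (3:12))
  expect_true(all(diff(h$table$mean_std) > 0)) # non-decreasing for a walk
  expect_error(hurst_exponent(rnorm(100), window_lengths = c(8, 16)),
               class = "critsig_insufficient_data")
})

test_that("decay fits recover forced exponential time constants", {
  d <- fit_decay(100 * exp(-(1:40) / 7))
  expect_equal(d$tau_decay, 7, tolerance = 1e-6)
  expect_equal(d$direction, "decay")
  g <- fit_decay(5 * exp((1:40) / 3))
  expect_equal(g$tau_decay, 3, tolerance = 1e-6)
  expect_equal(g$direction, "growth")
})

test_that("decay fit recovers tau = 12 from 5% noise within 10%", {
  set.seed(8)
  reps <- replicate(30, 80 * exp(-(1:40) / 12) * (1 + rnorm(40, 0, 0.05)))
  d <- fit_decay(rowMeans(reps))
  expect_equal(d$tau_decay, 12, tolerance = 0.1)
})

test_that("decay fit is invariant to uniform amplitude scaling", {
  set.seed(9)
  y <- 50 * exp(-(1:40) / 9) * (1 + rnorm(40, 0, 0.03))
  expect_equal(fit_decay(y)$tau_decay, fit_decay(1000 * y)$tau_decay,
               tolerance = 1e-6)
})

test_that("an all-zero window cannot be fitted", {
  expect_error(fit_decay(rep(0, 50)), class = "critsig_undefined_fit")
})

test_that("branching ratio arithmetic matches hand computation", {
  expect_equal(branching_ratio(rep(5, 10))$sigma, 1)
  b <- branching_ratio(c(4, 2, 1, 0))
  expect_equal(b$sigma, (2 / 4 + 1 / 2 + 0 / 1) / 3)
  expect_equal(b$n_pairs, 3L)
  expect_error(branching_ratio(c(0, 0, 0)), class = "critsig_undefined")
  expect_error(branching_ratio(5), class = "critsig_invalid_parameter")
})

test_that("branching ratio recovers the offspring mean of a Galton-Watson
           process", {
  set.seed(21)
  sigma_true <- 0.9
  counts <- numeric(0)
  for (i in 1:2000) {
    a <- 10
    while (a > 0 && length(counts) < 1e5) {
      counts <- c(counts, a)
      a <- rpois(1, sigma_true * a)
    }
    counts <- c(counts, 0)
  }
  est <- branching_ratio(counts)
  expect_equal(est$sigma, sigma_true, tolerance = 0.02)
})
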