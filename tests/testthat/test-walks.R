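test_that("the six-flip worked example gives heights 1,2,3,2,1,0", {
  w <- coin_flip_walk(flips = c("H", "H", "H", "T", "T", "T"))
  expect_equal(w$value, c(1, 2, 3, 2, 1, 0))
})

test_that("deterministic all-heads walk climbs linearly", {
  w <- coin_flip_walk(5, p_heads = 1, seed = 1)
  expect_equal(w$value, 1:5)
})

test_that("reflected walks stay non-negative and move by one per step", {
  for (s in 1:5) {
    w <- coin_flip_walk(5000, seed = s)
    expect_true(all(w$value >= 0))
    steps <- diff(c(0, w$value))
    # at the origin reflection forces a step up; elsewhere +/-1
    expect_true(all(abs(steps) == 1))
    at_zero <- which(w$value == 0)
    at_zero <- at_zero[at_zero < nrow(w)]
    expect_true(all(w$value[at_zero + 1] == 1))
  }
})

test_that("time at the origin matches the exact return probabilities", {
  n <- 12
  expected <- oracle_zero_fraction(n)
  set.seed(42)
  frac <- mean(vapply(1:4000, function(i) {
    mean(coin_flip_walk(n)$value == 0)
  }, numeric(1)))
  expect_equal(frac, expected, tolerance = 0.05)
})

test_that("walks are bit-identical under equal seeds", {
  expect_identical(coin_flip_walk(1000, seed = 7), coin_flip_walk(1000, seed = 7))
  expect_identical(ou_walk(1000, seed = 7), ou_walk(1000, seed = 7))
  expect_false(identical(coin_flip_walk(1000, seed = 7)$value,
                         coin_flip_walk(1000, seed = 8)$value))
})

test_that("invalid walk parameters are rejected", {
  expect_error(coin_flip_walk(0), class = "critsig_invalid_parameter")
  expect_error(coin_flip_walk(10, p_heads = 1.2),
               class = "critsig_invalid_parameter")
  expect_error(ou_walk(100, eta = 1.5), class = "critsig_invalid_parameter")
})

test_that("OU process with vanishing noise is identically zero", {
  w <- ou_walk(100, eta = 0.1, noise_scale = 0, seed = 1)
  expect_equal(w$value, rep(0, 100))
})

test_that("OU stationary variance matches the AR(1) closed form", {
  eta <- 0.05
  s <- 2
  w <- ou_walk(4e5, eta = eta, noise_scale = s, seed = 3)
  v_expected <- (1 - eta) ^ 2 * s ^ 2 / (1 - (1 - eta) ^ 2)
  v_sample <- var(w$value[-(1:1000)]) # discard the transient
  expect_equal(v_sample, v_expected, tolerance = 0.1)
})

test_that("OU with no feedback is a plain random walk (Hurst near 0.5)", {
  w <- ou_walk(2^18, eta = 0, noise_scale = 1, seed = 9)
  expect_equal(hurst_exponent(w)$H, 0.5, tolerance = 0.07)
})

test_that("streaming excursion statistics match the trace route", {
  n <- 1e5
  avs_stream <- coin_flip_avalanches(n, seed = 31)
  w <- coin_flip_walk(n, seed = 31)
  avs_trace <- walk_avalanches(w)
  expect_equal(avs_stream$duration, avs_trace$duration)
  expect_equal(avs_stream$size, avs_trace$size)
})

test_that("walk_to_raster activates round(gain * height) distinct neurons", {
  trace <- coin_flip_walk(flips = c("H", "H", "T", "T"))
  trace$value <- c(2, 3, 1, 0) # forced heights
  r <- walk_to_raster(trace, n_neurons = 20, gain = 3, seed = 4)
  counts <- population_counts(r)$count
  expect_equal(counts, c(6, 9, 3, 0))
  expect_false(anyDuplicated(r[c("neuron", "bin")]) > 0)
})

test_that("walk_to_raster conserves activity and clips with a warning", {
  w <- coin_flip_walk(500, seed = 6)
  r <- walk_to_raster(w, n_neurons = 1000, gain = 1, seed = 6)
  expect_equal(nrow(r), sum(round(w$value)))
  expect_warning(walk_to_raster(w, n_neurons = 3, gain = 5, seed = 6),
                 "clipped")
})

test_that("subthreshold traces produce an all-zero raster", {
  w <- ou_walk(50, noise_scale = 0, seed = 2)
  r <- walk_to_raster(w, n_neurons = 10)
  expect_equal(nrow(r), 0L)
})
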