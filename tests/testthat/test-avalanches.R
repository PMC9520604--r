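test_that("raster avalanches match the brute-force run-length oracle", {
  set.seed(14)
  for (i in 1:20) {
    r <- random_toy_raster(5, 20, p = 0.2)
    avs <- extract_avalanches(r)
    ora <- oracle_avalanches(population_counts(r)$count)
    expect_equal(avs$duration, as.integer(ora$duration))
    expect_equal(avs$size, ora$size)
  }
})

test_that("avalanche sizes conserve the spikes in bracketed bins", {
  set.seed(15)
  r <- random_toy_raster(8, 50, p = 0.15)
  counts <- population_counts(r)$count
  avs <- extract_avalanches(r)
  ora <- oracle_avalanches(counts)
  expect_equal(sum(avs$size), sum(ora$size))
})

test_that("edge-touching runs are discarded and empty rasters give none", {
  m <- matrix(0L, 3, 6)
  m[1, 1:2] <- 1L  # touches the left edge
  m[2, 4] <- 1L    # bracketed
  m[3, 6] <- 1L    # touches the right edge
  avs <- extract_avalanches(as_spike_raster(m))
  expect_equal(nrow(avs), 1L)
  expect_equal(avs$start_bin, 4L)
  expect_equal(nrow(extract_avalanches(as_spike_raster(matrix(0L, 3, 5)))), 0L)
})

test_that("the six-flip excursion has size 9 and duration 6", {
  avs <- walk_avalanches(fixture("coin6"))
  expect_equal(avs$size, 9)
  expect_equal(avs$duration, 6L)
})

test_that("walk avalanches require a reflected trace", {
  w <- coin_flip_walk(100, reflect = FALSE, seed = 2)
  expect_error(walk_avalanches(w), class = "critsig_precondition")
  expect_equal(nrow(walk_avalanches(ou_walk(50, noise_scale = 0))), 0L)
})

test_that("walk and raster routes agree on sizes; durations differ by the
           returning zero step", {
  # The flip-count convention includes the step that lands back on zero
  # (duration 6 for the six-flip example); the raster route sees only the
  # positive bins (duration 5).  Sizes are identical.
  w <- coin_flip_walk(1e4, seed = 8)
  via_walk <- walk_avalanches(w)
  r <- walk_to_raster(w, n_neurons = max(w$value) + 1, gain = 1, seed = 8)
  via_raster <- extract_avalanches(r)
  skip_first <- if (via_walk$start_bin[1] == 1) -1 else TRUE
  vw <- via_walk[skip_first, ]
  expect_equal(nrow(vw), nrow(via_raster))
  expect_equal(vw$size, via_raster$size)
  expect_equal(vw$duration, via_raster$duration + 1L)
})

test_that("exponent relation reproduces the worked predictions", {
  r <- exponent_relation(1.5, 1.9, 1.5)
  expect_equal(r$gamma_predicted, 1.8)
  expect_equal(exponent_relation(2, 2, 1)$relation_error_pct, 0)
  # at three printed decimals, (1.49 - 1)/(1.32 - 1) = 1.53125, i.e. a
  # 2.08% discrepancy against gamma = 1.50 (a fitted, unrounded triplet
  # in that neighbourhood gives ~3%)
  r2 <- exponent_relation(1.32, 1.49, 1.50)
  expect_equal(r2$relation_error_pct, 100 * (0.49 / 0.32 / 1.5 - 1),
               tolerance = 1e-10)
  expect_error(exponent_relation(1, 1.5, 1.5),
               class = "critsig_invalid_parameter")
})

test_that("size-duration scaling recovers forced exponents", {
  avs <- tibble::tibble(duration = rep(2:40, each = 3),
                        size = rep(2:40, each = 3) ^ 2)
  fit <- size_duration_scaling(avs, min_count = 1)
  expect_equal(fit$gamma, 2, tolerance = 1e-10)
  # two noiseless classes: slope equals the two-point log ratio
  two <- tibble::tibble(duration = c(10, 20, 10, 20), size = c(50, 210, 50, 210))
  fit2 <- size_duration_scaling(two, min_count = 1)
  expect_equal(fit2$gamma, log(210 / 50) / log(2))
  expect_error(size_duration_scaling(tibble::tibble(duration = rep(3, 20),
                                                    size = rep(9, 20))),
               class = "critsig_insufficient_data")
})

test_that("average shapes are elementwise means per duration class", {
  avs <- tibble::tibble(
    avalanche_id = 1:3, start_bin = c(2L, 10L, 20L),
    duration = c(3L, 3L, 5L), size = c(4, 8, 10),
    heights = list(c(1, 2, 1), c(3, 2, 3), c(2, 2, 2, 2, 2)))
  sh <- average_shapes(avs, durations = 3, min_count = 2)
  expect_equal(sh$shape[[1]], c(2, 2, 2))
  expect_warning(average_shapes(avs, durations = c(3, 5), min_count = 2),
                 "skipping")
  one <- suppressWarnings(average_shapes(avs, durations = 5, min_count = 1))
  expect_equal(one$shape[[1]], c(2, 2, 2, 2, 2))
})

test_that("self-similar parabolas collapse at gamma 1.5; tents never do", {
  par_fix <- fixture("parabolas_gamma1.5")
  free <- shape_collapse(par_fix)
  expect_equal(free$gamma_used, 1.5, tolerance = 0.011)
  expect_lt(free$collapse_error, 1e-3)

  tents <- fixture("tents")
  tent_best <- shape_collapse(tents)
  expect_gt(tent_best$collapse_error, 0.01) # bounded away from zero
  expect_gt(tent_best$collapse_error, 10 * free$collapse_error)
  expect_error(shape_collapse(par_fix[1:2, ]),
               class = "critsig_insufficient_data")
})

test_that("collapse error is invariant to uniform scaling of all shapes", {
  fix <- fixture("parabolas_gamma1.5")
  scaled <- fix
  scaled$shape <- lapply(scaled$shape, function(h) 37 * h)
  a <- shape_collapse(fix, gamma = 1.3)
  b <- shape_collapse(scaled, gamma = 1.3)
  expect_equal(a$collapse_error, b$collapse_error, tolerance = 1e-10)
})
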