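test_that("a 1000-neuron network at 10% density has 100,000 connections", {
  net <- build_brunel(brunel_config(n_neurons = 1000), seed = 1)
  expect_equal(net$n_connections, 100000L)
})

test_that("every neuron has the exact fixed in-degree and no self-loops", {
  cfg <- brunel_config(n_neurons = 200)
  net <- build_brunel(cfg, seed = 2)
  ce <- round(0.1 * 0.8 * 200)
  ci <- round(0.1 * 0.2 * 200)
  indeg <- tabulate(net$targ_idx + 1L, nbins = 200)
  expect_true(all(indeg == ce + ci))
  expect_true(all(net$src_sorted - 1L != net$targ_idx))
  # inhibitory weights are -g * j_excit
  w <- critsig:::edge_weights(net)
  expect_equal(sort(unique(w)), c(-cfg$g * cfg$j_excit, cfg$j_excit))
})

test_that("zero density gives an empty, non-recurrent network", {
  cfg <- brunel_config(n_neurons = 50, connection_density = 0)
  net <- build_brunel(cfg, seed = 3)
  expect_equal(net$n_connections, 0L)
})

test_that("adjacency depends only on the seed, not on g", {
  cfg1 <- brunel_config(n_neurons = 100, g = 1.5)
  cfg2 <- brunel_config(n_neurons = 100, g = 6)
  n1 <- build_brunel(cfg1, seed = 7)
  n2 <- build_brunel(cfg2, seed = 7)
  expect_identical(n1$targ_idx, n2$targ_idx)
})

test_that("no stimulus, no noise and a cold start stay silent", {
  cfg <- brunel_config(n_neurons = 100, v_init_max = 0)
  net <- build_brunel(cfg, seed = 4)
  r <- simulate_brunel(net, 50, seed = 1)
  expect_equal(nrow(r), 0L)
})

test_that("a pulse is amplified at low g and extinguished at high g", {
  n <- 1000
  run_pulse <- function(g) {
    cfg <- brunel_config(n_neurons = n, g = g)
    net <- build_brunel(cfg, seed = 5)
    r <- simulate_brunel(net, 30, stimulus = list(magnitude = 320, t_stim = 2),
                         seed = 9)
    population_counts(r)$count
  }
  low <- run_pulse(1.5)
  high <- run_pulse(6)
  expect_gt(mean(low[10:30]), 100)   # grows toward saturation
  expect_equal(sum(high[8:30]), 0)   # damped within a few bins
  expect_lt(sum(high[3:7]), 200)
})

test_that("stimulus magnitude beyond N is rejected", {
  net <- build_brunel(brunel_config(n_neurons = 20), seed = 1)
  expect_error(simulate_brunel(net, 10, stimulus = list(magnitude = 25,
                                                        t_stim = 2)),
               class = "critsig_invalid_parameter")
})

test_that("a disconnected network echoes the correlated drive exactly", {
  cfg <- brunel_config(n_neurons = 64, connection_density = 0,
                       v_init_max = 0)
  net <- build_brunel(cfg, seed = 6)
  k <- c(0, 3, 7, 0, 12, 5, 0, 1, 0, 0)
  r <- simulate_brunel(net, 10, noise = list(drive_counts = k, n_driven = 20),
                       seed = 2)
  expect_equal(population_counts(r)$count, k)
  expect_true(all(r$neuron <= 20))
})

test_that("uncorrelated noise fires roughly N * p_spont neurons per bin", {
  cfg <- brunel_config(n_neurons = 500, connection_density = 0,
                       v_init_max = 0)
  net <- build_brunel(cfg, seed = 8)
  r <- simulate_brunel(net, 200, noise = list(p_spont = 0.1), seed = 3)
  expect_equal(mean(population_counts(r)$count), 50, tolerance = 0.05)
})

test_that("simulations are reproducible under equal seeds", {
  cfg <- brunel_config(n_neurons = 100)
  net <- build_brunel(cfg, seed = 10)
  a <- simulate_brunel(net, 20, stimulus = list(magnitude = 30, t_stim = 2),
                       seed = 11)
  b <- simulate_brunel(net, 20, stimulus = list(magnitude = 30, t_stim = 2),
                       seed = 11)
  expect_identical(raster_matrix(a), raster_matrix(b))
})

test_that("firing rate is spikes per neuron per bin", {
  m <- matrix(1L, 4, 5)
  expect_equal(firing_rate(as_spike_raster(m)), 1)
  m2 <- matrix(0L, 4, 5); m2[1, 2] <- 1L
  expect_equal(firing_rate(as_spike_raster(m2)), 1 / 20)
})

test_that("degenerate density errors at construction", {
  cfg <- brunel_config(n_neurons = 30, connection_density = 0.01)
  expect_error(build_brunel(cfg, seed = 1),
               class = "critsig_degenerate_network")
})
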