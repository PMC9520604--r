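#' Parameters for the sparse E/I integrate-and-fire network
#'
#' A Brunel-style network: `n_neurons` leaky integrate-and-fire neurons,
#' 80% excitatory / 20% inhibitory, randomly connected at 10% density with
#' fixed in-degree, excitatory efficacy `j_excit` (mV) and inhibitory
#' efficacy `-g * j_excit`.  The relative inhibition `g` is the control
#' parameter tuning the network between an amplified (active) phase at low
#' `g` and a damped (inactive) phase at high `g`, with a critical
#' transition near `g = 3` under pulse stimulation.
#'
#' Time is discretised in bins of `dt_ms`, equal to the synaptic delay, so
#' the delay is one bin; the refractory period rounds to one bin.  The
#' default efficacy is chosen so that a pulse activating about a third of
#' the neurons propagates marginally near `g = 3` (see the methods
#' vignette for the mean-field argument); the original model's published
#' constants assume a strong external Poisson drive that is absent here.
#'
#' @param n_neurons Network size `N`.
#' @param g Relative inhibitory strength (dimensionless).
#' @param frac_excitatory Fraction of excitatory neurons (default 0.8).
#' @param connection_density Fraction of possible connections present
#'   (default 0.1).
#' @param j_excit Excitatory synaptic efficacy in mV.  The default
#'   (`NULL`) fixes the product of efficacy and in-degree at 140 mV
#'   (1.4 mV at the reference in-degree of 100), which pins the
#'   pulse-propagation branching ratio, and hence the critical `g`, at
#'   the same place for every network size and density.
#' @param v_init_max Initial membrane potentials are drawn uniformly from
#'   `[0, v_init_max)` each run (default: the threshold), representing
#'   the residue of background drive before it was switched off.  A
#'   synaptic volley delivering `mu` mV then recruits about a fraction
#'   `mu / threshold` of its targets, so the population response is
#'   graded and the pulse branching ratio is well defined.  Set 0 to
#'   start all neurons at rest.
#' @param delay_ms Synaptic delay (default 1.8 ms = one bin).
#' @param membrane_tau_ms,threshold_v,reset_v,refractory_ms,dt_ms LIF
#'   constants (membrane time constant, firing threshold and reset above
#'   rest, absolute refractory period, integration bin).
#' @return A `brunel_config` list.
#' @export
brunel_config <- function(n_neurons = 1000, g = 3, frac_excitatory = 0.8,
                          connection_density = 0.1, j_excit = NULL,
                          delay_ms = 1.8, membrane_tau_ms = 20,
                          threshold_v = 20, reset_v = 10, refractory_ms = 2,
                          dt_ms = 1.8, v_init_max = threshold_v) {
  if (g < 0) abort_critsig("`g` must be non-negative.", "invalid_parameter")
  if (connection_density < 0 || connection_density > 1)
    abort_critsig("`connection_density` must lie in [0, 1].",
                  "invalid_parameter")
  if (is.null(j_excit)) {
    # fix the total recurrent strength J * K at 5 * threshold: with
    # membranes uniform below threshold the pulse branching ratio is
    # sigma(g) = (J K / theta) (0.8 - 0.2 g), which then crosses 1
    # exactly at g = 3; it also keeps the critical g from drifting with
    # network size or density (see the methods vignette)
    k <- connection_density * n_neurons
    j_excit <- if (k > 0) 5 * threshold_v / k else 1
  }
  structure(list(n_neurons = as.integer(n_neurons), g = g,
                 v_init_max = v_init_max,
                 frac_excitatory = frac_excitatory,
                 connection_density = connection_density, j_excit = j_excit,
                 delay_ms = delay_ms, membrane_tau_ms = membrane_tau_ms,
                 threshold_v = threshold_v, reset_v = reset_v,
                 refractory_ms = refractory_ms, dt_ms = dt_ms),
            class = "brunel_config")
}

#' Build the random connectivity of a Brunel-style network
#'
#' Every neuron receives exactly `round(density * N * 0.8)` excitatory and
#' `round(density * N * 0.2)` inhibitory inputs, drawn uniformly without
#' replacement and excluding self-connections, with weights `j_excit` and
#' `-g * j_excit`.  The adjacency depends only on `seed` (not on `g` or
#' `j_excit`), so sweeps over `g` and connection ablations can reuse
#' identical topologies.
#'
#' @param config A [brunel_config()].
#' @param seed Integer seed for the topology.
#' @return A `brunel_network` (compressed sparse representation over
#'   sources, plus the config).
#' @export
build_brunel <- function(config, seed = 1) {
  n <- config$n_neurons
  n_exc <- round(config$frac_excitatory * n)
  ce <- round(config$connection_density * n_exc)
  ci <- round(config$connection_density * (n - n_exc))
  if (config$connection_density > 0 && ce + ci < 1)
    abort_critsig("degenerate network: density * N < 1 input per neuron.",
                  "degenerate_network")
  set.seed(seed)
  if (ce + ci == 0) {
    src <- integer(0); dst <- integer(0)
  } else {
    exc_pool <- seq_len(n_exc)
    inh_pool <- seq.int(n_exc + 1, n)
    src <- integer(n * (ce + ci))
    dst <- integer(n * (ce + ci))
    pos <- 0L
    for (i in seq_len(n)) {
      pe <- if (i <= n_exc) exc_pool[-i] else exc_pool
      pi_ <- if (i > n_exc) inh_pool[-(i - n_exc)] else inh_pool
      s <- c(pe[sample.int(length(pe), ce)], pi_[sample.int(length(pi_), ci)])
      idx <- pos + seq_along(s)
      src[idx] <- s
      dst[idx] <- i
      pos <- pos + length(s)
    }
  }
  ord <- order(src)
  src <- src[ord]; dst <- dst[ord]
  ptr <- c(0L, cumsum(tabulate(src, nbins = n)))
  structure(list(targ_ptr = ptr, targ_idx = dst - 1L, src_sorted = src,
                 n_exc = n_exc, config = config, seed = seed,
                 n_connections = length(src)),
            class = "brunel_network")
}

#' @export
print.brunel_network <- function(x, ...) {
  cat(sprintf("Brunel-style network: N = %d (%d E / %d I), %d connections, g = %g\n",
              x$config$n_neurons, x$n_exc, x$config$n_neurons - x$n_exc,
              x$n_connections, x$config$g))
  invisible(x)
}

edge_weights <- function(network, config = network$config) {
  w <- ifelse(network$src_sorted <= network$n_exc, config$j_excit,
              -config$g * config$j_excit)
  as.numeric(w)
}

# g and j can be overridden without rebuilding the topology
lif_run <- function(network, n_bins, stim_neurons = integer(0), t_stim = -1L,
                    p_spont = 0, drive_counts = integer(0),
                    drive_pool = integer(0), return_raster = FALSE,
                    config = network$config) {
  cfg <- config
  leak <- exp(-cfg$dt_ms / cfg$membrane_tau_ms)
  ref_bins <- max(0L, as.integer(round(cfg$refractory_ms / cfg$dt_ms)))
  delay_bins <- max(1L, as.integer(round(cfg$delay_ms / cfg$dt_ms)))
  cpp_simulate_lif(network$targ_ptr, network$targ_idx,
                   edge_weights(network, cfg), cfg$n_neurons,
                   as.integer(n_bins), leak, cfg$threshold_v, cfg$reset_v,
                   ref_bins, delay_bins, as.integer(stim_neurons) - 1L,
                   as.integer(t_stim) - 1L, p_spont,
                   as.integer(drive_counts), as.integer(drive_pool) - 1L,
                   return_raster, cfg$v_init_max)
}

#' Simulate the network
#'
#' Runs the discrete-time LIF dynamics from rest.  A stimulus forces the
#' stated number of randomly chosen neurons to spike at `t_stim`;
#' uncorrelated noise adds independent Bernoulli(`p_spont`) forced spikes
#' per neuron per bin; correlated noise forces `drive_counts[t]` of the
#' `n_driven` designated neurons (neurons `1..n_driven`) to spike in bin
#' `t`.
#'
#' @param network A [build_brunel()] network.
#' @param duration_bins Number of bins to simulate.
#' @param stimulus `NULL` or `list(magnitude =, t_stim =)` (1-based bin).
#' @param noise `NULL` or a list with `p_spont` (uncorrelated mode) and/or
#'   `drive_counts` plus `n_driven` (correlated mode).
#' @param seed Optional integer seed.
#' @return A `spike_raster`.
#' @export
simulate_brunel <- function(network, duration_bins, stimulus = NULL,
                            noise = NULL, seed = NULL) {
  n <- network$config$n_neurons
  stim_neurons <- integer(0)
  t_stim <- -1L
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(stimulus)) {
    if (stimulus$magnitude > n)
      abort_critsig("stimulus magnitude exceeds network size.",
                    "invalid_parameter")
    if (duration_bins < stimulus$t_stim)
      abort_critsig("duration must cover the stimulation bin.",
                    "invalid_parameter")
    stim_neurons <- sample.int(n, stimulus$magnitude)
    t_stim <- stimulus$t_stim
  }
  p_spont <- noise$p_spont %||% 0
  drive_counts <- noise$drive_counts %||% integer(0)
  drive_pool <- if (length(drive_counts) > 0)
    seq_len(noise$n_driven %||% n) else integer(0)
  res <- lif_run(network, duration_bins, stim_neurons, t_stim, p_spont,
                 drive_counts, drive_pool, return_raster = TRUE)
  as_spike_raster(res$raster, bin_ms = network$config$dt_ms)
}

#' Stimulus-response trials for one network
#'
#' Delivers `n_trials` pulses per stimulus level (numbers of neurons
#' forced to spike at `t_stim`) and reads out the response as the mean
#' population count over `response_window` bins after the stimulus
#' (default bins 3-5).  With a correlated `drive_walk`, consecutive
#' trials consume consecutive segments of the drive so the background
#' evolves across trials like an ongoing process.
#'
#' @param network A `brunel_network`.
#' @param levels Stimulus magnitudes (default 8 equally spaced values
#'   `0, N/8, ..., 7N/8`).
#' @param n_trials Trials per level.
#' @param t_stim Stimulation bin (1-based, default 6).
#' @param response_window Bins after the stimulus for the readout.
#' @param p_spont Per-neuron per-bin spontaneous firing probability.
#' @param n_driven,drive_walk Correlated drive: a reflected walk trace (or
#'   numeric heights) converted to per-bin forced-spike counts
#'   `round(drive_gain * height)` among neurons `1..n_driven`.
#' @param drive_gain Neurons per unit drive height (default 3).
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial (`level`, `trial`, `response`)
#'   carrying attribute `mean_counts` (bins x levels matrix of
#'   trial-averaged population counts).
#' @export
run_stim_trials <- function(network, levels = NULL, n_trials = 30,
                            t_stim = 6, response_window = 3:5,
                            p_spont = 0, n_driven = 0, drive_walk = NULL,
                            drive_gain = 3, seed = NULL) {
  n <- network$config$n_neurons
  if (is.null(levels)) levels <- floor(n * (0:7) / 8)
  duration <- t_stim + max(response_window) + 1
  if (!is.null(seed)) set.seed(seed)
  drive_k <- NULL
  if (!is.null(drive_walk) && n_driven > 0) {
    h <- if (is.data.frame(drive_walk)) drive_walk$value else drive_walk
    need <- duration * n_trials * length(levels)
    if (length(h) < need)
      abort_critsig("drive walk shorter than the trial schedule.",
                    "invalid_parameter")
    drive_k <- pmin(as.integer(round_half_up(drive_gain * pmax(h, 0))),
                    n_driven)
  }
  pool <- seq_len(max(n_driven, 0))
  n_slots <- length(levels) * n_trials
  # stimulus levels are presented in random order: the drive walk drifts
  # slowly, so a level-ordered schedule would correlate drive height with
  # stimulus level
  slot_of <- if (is.null(drive_k)) seq_len(n_slots) else sample.int(n_slots)
  rows <- vector("list", n_slots)
  mean_counts <- matrix(0, duration, length(levels))
  idx <- 0L
  for (li in seq_along(levels)) {
    for (tr in seq_len(n_trials)) {
      idx <- idx + 1L
      stim <- if (levels[li] > 0) sample.int(n, levels[li]) else integer(0)
      dk <- if (is.null(drive_k)) integer(0) else
        drive_k[((slot_of[idx] - 1L) * duration + 1L):(slot_of[idx] * duration)]
      res <- lif_run(network, duration, stim, t_stim, p_spont, dk,
                     if (length(dk)) pool else integer(0))
      counts <- res$counts
      mean_counts[, li] <- mean_counts[, li] + counts / n_trials
      rows[[idx]] <- tibble(level = levels[li], trial = tr,
                            response = mean(counts[t_stim + response_window]))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_counts") <- mean_counts
  attr(out, "levels") <- levels
  out
}
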