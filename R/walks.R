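#' Simulate a (reflected) coin-flip random walk
#'
#' Runs a cumulative plus/minus-1 walk from the origin: each head moves the
#' walker up one step, each tail down one step.  With `reflect = TRUE` the
#' absolute value of the walk is returned, so every zero-to-zero excursion
#' is a non-negative "avalanche" whose height at any step is the net excess
#' of heads within the excursion.  A fair coin (`p_heads = 0.5`) sits
#' exactly at the symmetry point of this process; biasing the coin tunes it
#' into one of two phases (heads-dominated or tails-dominated) and destroys
#' the power-law excursion statistics.
#'
#' @param n_flips Number of flips (steps).
#' @param p_heads Probability of a head, in `[0, 1]`.
#' @param reflect If `TRUE` (default), return the absolute value of the
#'   cumulative walk.
#' @param seed Optional integer seed for reproducibility.
#' @param flips Optional character/logical vector of predetermined flips
#'   (`"H"`/`"T"` or `TRUE`/`FALSE`); overrides the random draw and
#'   `n_flips`.
#' @return A `walk_trace` tibble with columns `step` and `value`, carrying
#'   attributes `kind`, `params`, and `seed`.
#' @examples
#' coin_flip_walk(flips = c("H", "H", "H", "T", "T", "T"))$value
#' @export
coin_flip_walk <- function(n_flips = NULL, p_heads = 0.5, reflect = TRUE,
                           seed = NULL, flips = NULL) {
  if (!is.null(flips)) {
    if (is.character(flips)) flips <- toupper(flips) == "H"
    steps <- ifelse(flips, 1, -1)
    x <- cumsum(steps)
    if (reflect) x <- abs(x)
    return(new_walk_trace(x, kind = "coin_flip",
                          params = list(n_flips = length(flips),
                                        p_heads = NA_real_, reflect = reflect),
                          seed = seed))
  }
  check_coin_params(n_flips, p_heads)
  if (!is.null(seed)) set.seed(seed)
  x <- cpp_coin_walk(n_flips, p_heads, reflect)
  new_walk_trace(x, kind = "coin_flip",
                 params = list(n_flips = n_flips, p_heads = p_heads,
                               reflect = reflect),
                 seed = seed)
}

#' Simulate a thresholdable Ornstein-Uhlenbeck process
#'
#' Iterates `x[t+1] = x[t] - eta * x[t] + (1 - eta) * xi[t]` with Gaussian
#' increments `xi[t]` of standard deviation `noise_scale`, starting from
#' zero.  The negative-feedback term `-eta * x` pulls the walker back
#' toward the origin; with `eta = 0` the process is a pure Gaussian random
#' walk.  For `eta` in (0, 1) the stationary variance follows the AR(1)
#' closed form `(1 - eta)^2 * noise_scale^2 / (1 - (1 - eta)^2)`.
#'
#' @param n_steps Number of steps.
#' @param eta Feedback strength per step, in `[0, 1]`.  The default 0.001
#'   keeps the process walk-like at avalanche timescales.
#' @param noise_scale Standard deviation of the per-step Gaussian increment.
#' @param seed Optional integer seed.
#' @return A `walk_trace` tibble (columns `step`, `value`).
#' @export
ou_walk <- function(n_steps, eta = 0.001, noise_scale = 1, seed = NULL) {
  if (!is.numeric(n_steps) || n_steps < 1)
    abort_critsig("`n_steps` must be a positive integer.", "invalid_parameter")
  if (eta < 0 || eta > 1)
    abort_critsig("`eta` must lie in [0, 1]: larger feedback overshoots.",
                  "invalid_parameter")
  if (noise_scale < 0)
    abort_critsig("`noise_scale` must be non-negative.", "invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  x <- cpp_ou_walk(n_steps, eta, noise_scale)
  new_walk_trace(x, kind = "ou",
                 params = list(n_steps = n_steps, eta = eta,
                               noise_scale = noise_scale),
                 seed = seed)
}

#' Simulate a persistent (correlated) plus/minus-1 walk
#'
#' Each step repeats the direction of the previous step with probability
#' `persist`.  `persist = 0.5` recovers the memoryless walk (Hurst exponent
#' near 0.5); `persist > 0.5` yields a persistent walk with long-range
#' temporal correlations (H above 0.5); `persist < 0.5` an antipersistent
#' one (H below 0.5).
#'
#' @param n_steps Number of steps.
#' @param persist Probability of repeating the previous direction.
#' @param seed Optional integer seed.
#' @return A `walk_trace` tibble (columns `step`, `value`).
#' @export
persistent_walk <- function(n_steps, persist = 0.5, seed = NULL) {
  if (persist < 0 || persist > 1)
    abort_critsig("`persist` must lie in [0, 1].", "invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  x <- cpp_persistent_walk(n_steps, persist)
  new_walk_trace(x, kind = "persistent",
                 params = list(n_steps = n_steps, persist = persist),
                 seed = seed)
}

#' Zero-to-zero excursion statistics of a long reflected coin-flip walk
#'
#' Streams a reflected coin-flip walk of arbitrary length (billions of
#' flips fit in constant memory) and records every zero-to-zero excursion
#' as an avalanche: its duration is the number of flips in the excursion
#' (the worked six-flip example H,H,H,T,T,T has duration 6) and its size
#' the summed heights (9 for that example).  Height profiles are
#' accumulated for durations up to `shape_max_t` so average avalanche
#' shapes and shape collapse can be computed without storing the trace.
#' A trailing excursion that has not returned to zero is discarded.
#'
#' @param n_flips Number of flips.
#' @param p_heads Probability of a head.
#' @param seed Optional integer seed.
#' @param shape_max_t Longest duration for which height profiles are
#'   accumulated (default 64).
#' @return An `avalanche_set` tibble with columns `avalanche_id`,
#'   `duration`, `size`, carrying an attribute `shapes`: a tibble of mean
#'   height profiles (`duration`, `n`, `shape` list-column).
#' @export
coin_flip_avalanches <- function(n_flips, p_heads = 0.5, seed = NULL,
                                 shape_max_t = 64) {
  check_coin_params(n_flips, p_heads)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_coin_excursions(n_flips, p_heads, shape_max_t)
  shapes <- shape_table(res$shape_sums, res$shape_counts)
  avs <- tibble(avalanche_id = seq_along(res$duration),
                duration = res$duration, size = res$size)
  new_avalanche_set(avs, source = "coin_flip", shapes = shapes)
}

shape_table <- function(shape_sums, shape_counts) {
  keep <- which(shape_counts > 0) # index k corresponds to duration k - 1
  tibble(
    duration = keep - 1L,
    n = shape_counts[keep],
    shape = lapply(keep, function(k) {
      T <- k - 1L
      shape_sums[k, seq_len(T)] / shape_counts[k]
    })
  )
}

#' Threshold a walk trace into a spike raster
#'
#' Converts a scalar trace into population spiking: in each time bin the
#' number of active neurons is `round(gain * max(x - threshold, 0))`,
#' clipped to `n_neurons`, and that many distinct neurons are chosen
#' uniformly at random.  With the default `gain = 3`, a trace value of 2
#' activates six neurons.  Rounding is half-away-from-zero.
#'
#' @param trace A `walk_trace` tibble (or any data frame with a `value`
#'   column).
#' @param n_neurons Number of neurons in the raster (default 128).
#' @param gain Neurons activated per unit height above threshold
#'   (default 3).
#' @param threshold Threshold subtracted from the trace (default 0).
#' @param seed Optional integer seed for the neuron draws.
#' @return A `spike_raster` (sparse tibble of `neuron`, `bin`; see
#'   [as_spike_raster()]).
#' @export
walk_to_raster <- function(trace, n_neurons = 128, gain = 3, threshold = 0,
                           seed = NULL) {
  if (gain <= 0) abort_critsig("`gain` must be positive.", "invalid_parameter")
  x <- trace$value
  if (any(!is.finite(x)))
    abort_critsig("trace values must be finite.", "invalid_parameter")
  k <- round_half_up(gain * pmax(x - threshold, 0))
  if (any(k > n_neurons)) {
    warning(sprintf("drive exceeds n_neurons in %d bins; counts clipped to %d",
                    sum(k > n_neurons), n_neurons))
    k <- pmin(k, n_neurons)
  }
  if (!is.null(seed)) set.seed(seed)
  bins <- rep.int(seq_along(k), k)
  neurons <- unlist(lapply(k[k > 0], function(kk) sample.int(n_neurons, kk)),
                    use.names = FALSE)
  new_spike_raster(tibble(neuron = as.integer(neurons),
                          bin = as.integer(bins)),
                   n_neurons = n_neurons, n_bins = length(k), bin_ms = 1)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

check_coin_params <- function(n_flips, p_heads) {
  if (!is.numeric(n_flips) || length(n_flips) != 1 || n_flips < 1)
    abort_critsig("`n_flips` must be a positive count.", "invalid_parameter")
  if (p_heads < 0 || p_heads > 1)
    abort_critsig("`p_heads` must lie in [0, 1].", "invalid_parameter")
}

new_walk_trace <- function(values, kind, params, seed) {
  out <- tibble(step = seq_along(values), value = as.numeric(values))
  class(out) <- c("walk_trace", class(out))
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}
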