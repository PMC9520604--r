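# Brute-force oracles used across test files.

# run-length scan over population counts: the independent avalanche oracle
oracle_avalanches <- function(counts) {
  out <- list()
  cur <- NULL
  for (t in seq_along(counts)) {
    if (counts[t] > 0) {
      cur <- c(cur, counts[t])
    } else if (!is.null(cur)) {
      out[[length(out) + 1]] <- list(start = t - length(cur), heights = cur)
      cur <- NULL
    }
  }
  # drop runs touching either edge (cannot verify bracketing)
  keep <- vapply(out, function(a) a$start > 1, logical(1))
  out <- out[keep]
  data.frame(duration = vapply(out, function(a) length(a$heights), numeric(1)),
             size = vapply(out, function(a) sum(a$heights), numeric(1)))
}

# expected fraction of steps at the origin for an n-step fair walk:
# mean over t of P(x_t = 0), with P(x_{2k} = 0) = C(2k, k) / 4^k
oracle_zero_fraction <- function(n) {
  p <- vapply(seq_len(n), function(t) {
    if (t %% 2 == 1) 0 else choose(t, t / 2) / 4 ^ (t / 2)
  }, numeric(1))
  mean(p)
}

random_toy_raster <- function(n_neurons = 5, n_bins = 20, p = 0.25) {
  m <- matrix(rbinom(n_neurons * n_bins, 1, p), n_neurons, n_bins)
  as_spike_raster(m)
}
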