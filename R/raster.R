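#' Sparse spike rasters
#'
#' A `spike_raster` is a sparse tibble of spikes with 0/1 semantics: one
#' row per (neuron, bin) pair, using 1-based indices internally, plus
#' attributes `n_neurons`, `n_bins`, and `bin_ms`.  It is the common
#' currency between the network simulator, the thresholded-walk null
#' models, and the avalanche statistics.
#'
#' @param x For `as_spike_raster()`: a binary matrix (neurons x bins) or a
#'   data frame with columns `neuron` and `bin` (1-based).
#' @param n_neurons,n_bins Raster dimensions (required for data-frame
#'   input; inferred from matrices).
#' @param bin_ms Width of a time bin in milliseconds.
#' @return A `spike_raster` tibble.
#' @export
as_spike_raster <- function(x, n_neurons = NULL, n_bins = NULL, bin_ms = 1) {
  if (is.matrix(x)) {
    stopifnot(all(x %in% c(0, 1)))
    idx <- which(x == 1, arr.ind = TRUE)
    return(new_spike_raster(
      tibble(neuron = as.integer(idx[, 1]), bin = as.integer(idx[, 2])),
      n_neurons = nrow(x), n_bins = ncol(x), bin_ms = bin_ms))
  }
  stopifnot(is.data.frame(x), all(c("neuron", "bin") %in% names(x)))
  if (is.null(n_neurons) || is.null(n_bins))
    abort_critsig("`n_neurons` and `n_bins` are required for data-frame input.",
                  "invalid_parameter")
  new_spike_raster(tibble(neuron = as.integer(x$neuron),
                          bin = as.integer(x$bin)),
                   n_neurons = n_neurons, n_bins = n_bins, bin_ms = bin_ms)
}

new_spike_raster <- function(df, n_neurons, n_bins, bin_ms) {
  if (nrow(df) > 0) {
    stopifnot(all(df$neuron >= 1), all(df$neuron <= n_neurons),
              all(df$bin >= 1), all(df$bin <= n_bins))
    if (anyDuplicated(df[c("neuron", "bin")]) > 0)
      abort_critsig("duplicate (neuron, bin) spike entries.", "parse_error")
  }
  class(df) <- c("spike_raster", class(df))
  attr(df, "n_neurons") <- as.integer(n_neurons)
  attr(df, "n_bins") <- as.integer(n_bins)
  attr(df, "bin_ms") <- bin_ms
  df
}

#' @rdname as_spike_raster
#' @param raster A `spike_raster`.
#' @export
raster_matrix <- function(raster) {
  m <- matrix(0L, attr(raster, "n_neurons"), attr(raster, "n_bins"))
  if (nrow(raster) > 0) m[cbind(raster$neuron, raster$bin)] <- 1L
  m
}

#' Per-bin population activity of a raster
#'
#' Column sums of the binary raster: the number of neurons active in each
#' time bin, the quantity from which avalanches and branching ratios are
#' computed.
#'
#' @param raster A `spike_raster`.
#' @return A tibble with columns `bin` and `count` covering every bin.
#' @export
population_counts <- function(raster) {
  n_bins <- attr(raster, "n_bins")
  counts <- tabulate(raster$bin, nbins = n_bins)
  tibble(bin = seq_len(n_bins), count = counts)
}

#' Mean firing rate of a raster
#'
#' Total spikes divided by (neurons x bins): mean spikes per neuron per
#' bin.  Used as the order parameter of the network phase transition.
#'
#' @param raster A `spike_raster`.
#' @return A single non-negative number (spikes per neuron per bin).
#' @export
firing_rate <- function(raster) {
  n <- attr(raster, "n_neurons") * attr(raster, "n_bins")
  if (is.null(n) || n == 0)
    abort_critsig("empty raster.", "invalid_parameter")
  nrow(raster) / n
}

#' Read and write sparse spike-list files
#'
#' The on-disk format is a CSV of `neuron_id,time_bin` pairs (0-based,
#' half-open bin indexing) preceded by a single header comment line
#' `# n_neurons=<N> n_bins=<T> bin_ms=<w>`.  Round trips are lossless.
#'
#' @param raster A `spike_raster`.
#' @param path File path.
#' @return `read_spike_list()` returns a `spike_raster`;
#'   `write_spike_list()` returns `path` invisibly.
#' @export
write_spike_list <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d n_bins=%d bin_ms=%g",
                     attr(raster, "n_neurons"), attr(raster, "n_bins"),
                     attr(raster, "bin_ms")), con)
  writeLines("neuron_id,time_bin", con)
  if (nrow(raster) > 0) {
    ord <- order(raster$bin, raster$neuron)
    writeLines(paste(raster$neuron[ord] - 1L, raster$bin[ord] - 1L, sep = ","),
               con)
  }
  invisible(path)
}

#' @rdname write_spike_list
#' @export
read_spike_list <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("# n_neurons=(\\d+) n_bins=(\\d+) bin_ms=([0-9.]+)",
                          header))[[1]]
  if (length(m) != 4)
    abort_critsig(sprintf("line 1: malformed spike-list header: %s", header),
                  "parse_error")
  n_neurons <- as.integer(m[2]); n_bins <- as.integer(m[3])
  bin_ms <- as.numeric(m[4])
  df <- read.csv(path, skip = 1)
  if (!identical(names(df), c("neuron_id", "time_bin")))
    abort_critsig("line 2: expected columns neuron_id,time_bin.", "parse_error")
  if (nrow(df) > 0) {
    bad <- which(df$neuron_id < 0 | df$neuron_id >= n_neurons |
                   df$time_bin < 0 | df$time_bin >= n_bins)
    if (length(bad) > 0)
      abort_critsig(sprintf("line %d: id or bin out of range.", bad[1] + 2),
                    "parse_error")
  }
  new_spike_raster(tibble(neuron = df$neuron_id + 1L, bin = df$time_bin + 1L),
                   n_neurons = n_neurons, n_bins = n_bins, bin_ms = bin_ms)
}

#' Read and write walk traces as two-column CSV
#'
#' @param trace A `walk_trace`.
#' @param path File path.
#' @return `read_walk()` returns a `walk_trace`; `write_walk()` returns
#'   `path` invisibly.
#' @export
write_walk <- function(trace, path) {
  write.csv(trace[c("step", "value")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk
#' @export
read_walk <- function(path) {
  df <- read.csv(path)
  if (!all(c("step", "value") %in% names(df)))
    abort_critsig("expected columns step,value.", "parse_error")
  new_walk_trace(df$value, kind = "file", params = list(path = path),
                 seed = NULL)
}
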