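#' Discretise scalar responses into equal-width bins
#'
#' Integer symbols from equal-width bins spanning the observed range.
#' Constant responses collapse to a single symbol (entropy 0), which is a
#' valid outcome, not an error.
#'
#' @param responses Finite numeric vector.
#' @param n_bins Number of bins (default 8, matching an 8-level stimulus
#'   alphabet so the mutual information is capped at 3 bits by design).
#' @return Integer vector of symbols in `1..n_bins`.
#' @export
bin_responses <- function(responses, n_bins = 8) {
  if (any(!is.finite(responses)))
    abort_critsig("responses must be finite.", "invalid_parameter")
  rng <- range(responses)
  if (diff(rng) == 0) return(rep(1L, length(responses)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pmin(pmax(findInterval(responses, edges, rightmost.closed = TRUE), 1L),
       n_bins)
}

plugin_entropy <- function(symbols) {
  p <- table(symbols) / length(symbols)
  -sum(p * log2(p))
}

#' Stimulus-response entropies and mutual information
#'
#' Plug-in (maximum-likelihood) estimates in bits over discretised
#' responses: the response entropy `H(R)` (the information capacity), the
#' conditional entropy `H(R|S) = sum_s p(s) H(R|s)`, and their difference,
#' the mutual information `MI(S;R) = H(R) - H(R|S)`.  High MI needs both a
#' wide variety of responses (large `H(R)`) and reliable responses per
#' stimulus (small `H(R|S)`).  Plug-in estimates carry an upward bias at
#' small trial counts that shrinks as trials grow.
#'
#' @param data A data frame of trials.
#' @param stimulus,response Column names (character) of the stimulus level
#'   and the scalar response.
#' @param n_bins Response bins (default 8); responses are passed through
#'   [bin_responses()] unless `already_binned`.
#' @param already_binned If `TRUE`, `response` is taken as discrete
#'   symbols.
#' @return A one-row tibble: `H_R`, `H_R_given_S`, `MI` (bits),
#'   `n_levels`, `n_trials`.
#' @export
response_entropies <- function(data, stimulus = "stimulus",
                               response = "response", n_bins = 8,
                               already_binned = FALSE) {
  if (nrow(data) == 0) abort_critsig("empty trial table.", "invalid_parameter")
  s <- data[[stimulus]]
  r <- data[[response]]
  sym <- if (already_binned) r else bin_responses(r, n_bins)
  h_r <- plugin_entropy(sym)
  by_s <- split(sym, s)
  p_s <- vapply(by_s, length, numeric(1)) / length(sym)
  h_rs <- sum(p_s * vapply(by_s, plugin_entropy, numeric(1)))
  tibble(H_R = h_r, H_R_given_S = h_rs, MI = h_r - h_rs,
         n_levels = length(by_s), n_trials = nrow(data))
}

#' Entropies from a joint stimulus-response count table
#'
#' Direct computation from a joint contingency matrix (rows = stimulus
#' levels, columns = response symbols); the independent oracle against
#' which trial-table estimates are checked.
#'
#' @param counts Numeric matrix of joint counts.
#' @return A one-row tibble: `H_R`, `H_R_given_S`, `MI` (bits).
#' @export
joint_table_entropies <- function(counts) {
  p <- counts / sum(counts)
  p_r <- colSums(p)
  p_s <- rowSums(p)
  h_r <- -sum(p_r[p_r > 0] * log2(p_r[p_r > 0]))
  h_rs <- sum(vapply(seq_len(nrow(p)), function(i) {
    if (p_s[i] == 0) return(0)
    cond <- p[i, p[i, ] > 0] / p_s[i]
    -p_s[i] * sum(cond * log2(cond))
  }, numeric(1)))
  tibble(H_R = h_r, H_R_given_S = h_rs, MI = h_r - h_rs)
}
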