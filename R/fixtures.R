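#' Canned toy inputs
#'
#' Small, programmatically constructed inputs used in examples and tests:
#' \describe{
#'   \item{`"coin6"`}{the six-flip walk H,H,H,T,T,T with heights
#'     1,2,3,2,1,0 (one avalanche of duration 6 and size 9).}
#'   \item{`"toy_raster"`}{a 5-neuron, 7-bin raster whose single bracketed
#'     avalanche has a tent shape.}
#'   \item{`"parabolas_gamma1.5"`}{an exactly self-similar family of
#'     parabolic mean shapes `h_T(t) = T^0.5 * 4 * (t/T) * (1 - t/T)` for
#'     durations 10, 20, 40 (collapses perfectly at gamma = 1.5).}
#'   \item{`"tents"`}{tent shapes with equal peak heights but different
#'     durations: the counter-example family that cannot be collapsed by
#'     any single exponent.}
#'   \item{`"joint_mi_1.5bits"`}{a 4 x 4 joint stimulus-response count
#'     table whose mutual information is exactly 1.5 bits.}
#' }
#'
#' @param name Fixture name; an unknown name raises an error listing the
#'   available fixtures.
#' @return The fixture object (type depends on the fixture).
#' @export
fixture <- function(name) {
  fixtures <- list(
    coin6 = function() coin_flip_walk(flips = c("H", "H", "H", "T", "T", "T")),
    toy_raster = function() {
      m <- matrix(0L, 5, 7)
      m[1, 3] <- 1L
      m[c(2, 3), 4] <- 1L
      m[c(1, 3, 4), 5] <- 1L
      m[c(2, 5), 6] <- 1L
      as_spike_raster(m)
    },
    parabolas_gamma1.5 = function() {
      durations <- c(10, 20, 40)
      tibble(duration = durations,
             n = 1L,
             shape = lapply(durations, function(T) {
               s <- (seq_len(T) - 1) / (T - 1)
               T ^ 0.5 * 4 * s * (1 - s)
             }))
    },
    tents = function() {
      # equal peak heights, rise completed at a fixed absolute time, so the
      # falling slope is shallower for longer avalanches: no single
      # exponent can collapse these (heights match only at gamma = 1 but
      # the time-rescaled profiles then disagree)
      durations <- c(10, 20, 40)
      t_peak <- 5
      peak <- 10
      tibble(duration = durations,
             n = 1L,
             shape = lapply(durations, function(T) {
               t <- seq_len(T)
               ifelse(t <= t_peak, peak * t / t_peak,
                      peak * (T - t) / (T - t_peak))
             }))
    },
    joint_mi_1.5bits = function() {
      matrix(c(10, 0, 0, 0,
               0, 10, 0, 0,
               0, 0, 5, 5,
               0, 0, 5, 5), 4, 4, byrow = TRUE)
    })
  if (!name %in% names(fixtures))
    abort_critsig(sprintf("unknown fixture '%s'; available: %s", name,
                          paste(names(fixtures), collapse = ", ")),
                  "invalid_parameter")
  fixtures[[name]]()
}
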