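#' Hurst exponent by windowed standard-deviation scaling
#'
#' Breaks the series into disjoint windows of length `L` for a geometric
#' ladder of window sizes, averages the within-window standard deviations,
#' and estimates `H` as the slope of `log(mean STD)` against `log(L)`:
#' `STD(L t) = L^H STD(t)`.  A memoryless walk gives `H` near 0.5;
#' persistent (long-range correlated) processes give `H > 0.5`,
#' antipersistent ones `H < 0.5`, and i.i.d. noise a slope near 0.
#'
#' @param x Numeric series (e.g. walker positions), or a `walk_trace`.
#' @param window_lengths Ladder of window sizes; default powers of 2 from
#'   8 up to `length(x) / 8`.
#' @return A `hurst_estimate`; `glance()` gives `H`, `tidy()` the mean STD
#'   per window length.
#' @export
hurst_exponent <- function(x, window_lengths = NULL) {
  if (is.data.frame(x)) x <- x$value
  n <- length(x)
  if (is.null(window_lengths)) {
    max_l <- n / 8
    if (max_l < 8) abort_critsig("series too short for the default ladder.",
                                 "insufficient_data")
    window_lengths <- 2 ^ (3:floor(log2(max_l)))
  }
  if (length(window_lengths) < 3)
    abort_critsig("need at least 3 window sizes.", "insufficient_data")
  msd <- vapply(window_lengths, function(L) {
    m <- floor(n / L)
    xm <- matrix(x[seq_len(m * L)], nrow = L)
    mu <- colMeans(xm)
    mu2 <- colMeans(xm ^ 2)
    mean(sqrt(pmax(mu2 - mu ^ 2, 0) * L / (L - 1)))
  }, numeric(1))
  ok <- msd > 0
  fit <- lm(log(msd[ok]) ~ log(window_lengths[ok]))
  structure(list(H = unname(coef(fit)[2]),
                 table = tibble(window_length = window_lengths,
                                mean_std = msd)),
            class = "hurst_estimate")
}

#' @export
print.hurst_estimate <- function(x, ...) {
  cat(sprintf("Hurst exponent H = %.3f (windows %g..%g)\n", x$H,
              min(x$table$window_length), max(x$table$window_length)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.hurst_estimate <- function(x, ...) {
  tibble(H = x$H, n_windows = nrow(x$table))
}

#' @exportS3Method generics::tidy
tidy.hurst_estimate <- function(x, ...) x$table

#' Two-point Hurst exponent from a pair of standard deviations
#'
#' Solves `STD(L t) = L^H STD(t)` for `H` given standard deviations
#' measured at two durations a factor `L` apart; e.g. STDs of 70.26 and
#' 202.13 at `L = 8` give `H` of about 0.51.
#'
#' @param std_short,std_long Standard deviations at the shorter and longer
#'   duration.
#' @param L Ratio of the two durations.
#' @return The Hurst exponent.
#' @export
hurst_two_point <- function(std_short, std_long, L) {
  log(std_long / std_short) / log(L)
}

#' Exponential time constant of post-stimulus activity
#'
#' Fits `c + A * exp(b * t)` to (trial-averaged) population activity after
#' a stimulus by nonlinear least squares and reports the time constant
#' `tau = 1 / |b|`.  The baseline `c` lets the same form capture both
#' decays to silence (damped phase) and fast rises onto a saturation
#' plateau (amplified phase), which a pure exponential cannot represent:
#' both away-from-transition regimes then show short time constants, while
#' near the phase transition activity decays slowly and `tau` peaks
#' sharply.  The direction is the sign of the fitted trend over the
#' window.
#'
#' @param activity Non-negative numeric vector indexed by bins after the
#'   stimulus (element 1 = first post-stimulus bin).
#' @param fit_window Bins used for the fit (default 3:40).
#' @return A `decay_fit` with `tau_decay` (bins), `amplitude`, and
#'   `direction` (`"growth"` or `"decay"`).
#' @export
fit_decay <- function(activity, fit_window = 3:40) {
  fit_window <- fit_window[fit_window <= length(activity)]
  t <- fit_window
  y <- activity[fit_window]
  ok <- is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(y) < 4 || all(y == 0))
    abort_critsig("too few usable activity values in the fit window.",
                  "undefined_fit")

  # starting values: a log-linear fit on the positive values (exact for a
  # pure exponential) and a plateau variant (for saturating rises, where
  # the transient rides on a constant baseline)
  starts <- list()
  pos <- y > 0
  if (sum(pos) >= 3) {
    ll <- lm(log(y[pos]) ~ t[pos])
    starts$loglin <- list(c0 = 0, A = exp(unname(coef(ll)[1])),
                          b = unname(coef(ll)[2]))
  }
  plateau <- mean(y[t >= quantile(t, 0.75)])
  starts$plateau <- list(c0 = plateau, A = y[1] - plateau, b = -0.2)

  # bounds keep the baseline physical (activity cannot be negative) and
  # block the degenerate near-linear parameterisation c0 -> -Inf, b -> 0
  ymax <- max(y, 1e-9)
  lower <- c(c0 = 0, A = -3 * ymax, b = -3)
  upper <- c(c0 = ymax, A = 10 * ymax, b = 3)
  clamp <- function(s) as.list(pmin(pmax(unlist(s), lower + 1e-9),
                                    upper - 1e-9))
  # each start is itself a candidate (the log-linear one is exact for a
  # pure exponential, where nls can hit a numerically singular gradient);
  # nls refines it when it converges
  rss_of <- function(p) sum((y - (p[1] + p[2] * exp(p[3] * t))) ^ 2)
  best <- NULL
  consider <- function(p, best) {
    r <- rss_of(p)
    if (is.finite(r) && (is.null(best) || r < best$rss))
      list(par = p, rss = r) else best
  }
  for (s in starts) {
    best <- consider(unlist(s), best)
    fit <- tryCatch(
      nls(y ~ c0 + A * exp(b * t), start = clamp(s), algorithm = "port",
          lower = lower, upper = upper, control = list(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) best <- consider(coef(fit), best)
  }
  if (is.null(best))
    abort_critsig("exponential fit failed on this window.", "undefined_fit")
  co <- setNames(best$par, c("c0", "A", "b"))
  b <- unname(co["b"])
  yhat_first <- co["c0"] + co["A"] * exp(b * t[1])
  yhat_last <- co["c0"] + co["A"] * exp(b * t[length(t)])
  structure(list(tau_decay = 1 / max(abs(b), 1e-12),
                 amplitude = abs(unname(co["A"])),
                 offset = unname(co["c0"]),
                 direction = if (yhat_last > yhat_first) "growth" else "decay",
                 fit_window = range(t)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("exponential %s, tau = %.2f bins (window %d..%d)\n",
              x$direction, x$tau_decay, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble(tau_decay = x$tau_decay, amplitude = x$amplitude,
         direction = x$direction)
}

#' Naive branching ratio of a raster
#'
#' The average number of active descendants per active ancestor in the
#' next time bin: the mean of `A[t + 1] / A[t]` over bins with `A[t] > 0`,
#' where `A[t]` is the population count.  Values below 1 indicate the
#' damped (subcritical) phase, above 1 the amplified (supercritical)
#' phase, and 1 the critical point.  This is the naive estimator; it is
#' biased under subsampling.
#'
#' @param raster A `spike_raster`, or a numeric vector of population
#'   counts.
#' @return A tibble with `sigma` and `n_pairs` (ancestor bins used).
#' @export
branching_ratio <- function(raster) {
  counts <- if (is.numeric(raster)) raster else population_counts(raster)$count
  if (length(counts) < 2)
    abort_critsig("need at least 2 bins.", "invalid_parameter")
  a <- head(counts, -1)
  b <- tail(counts, -1)
  use <- a > 0
  if (!any(use))
    abort_critsig("no active ancestor bins; branching ratio undefined.",
                  "undefined")
  tibble(sigma = mean(b[use] / a[use]), n_pairs = sum(use))
}
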