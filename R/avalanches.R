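new_avalanche_set <- function(df, source, shapes = NULL, bin_ms = 1) {
  class(df) <- c("avalanche_set", class(df))
  attr(df, "source") <- source
  attr(df, "bin_ms") <- bin_ms
  if (!is.null(shapes)) attr(df, "shapes") <- shapes
  df
}

#' Extract neuronal avalanches from a spike raster
#'
#' An avalanche is a maximal run of consecutive time bins with nonzero
#' population activity, bracketed by silent bins.  Runs touching the first
#' or last bin of the raster are discarded because bracketing cannot be
#' verified there.  Heights are the per-bin population counts, the size is
#' their sum, and the duration is the number of active bins.
#'
#' @param raster A `spike_raster`.
#' @return An `avalanche_set` tibble with columns `avalanche_id`,
#'   `start_bin`, `duration`, `size`, and a `heights` list-column.
#' @export
extract_avalanches <- function(raster) {
  counts <- population_counts(raster)$count
  counts_to_avalanches(counts, source = "raster",
                       bin_ms = attr(raster, "bin_ms") %||% 1)
}

counts_to_avalanches <- function(counts, source, bin_ms = 1) {
  active <- counts > 0
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & starts > 1 & ends < length(counts)
  if (!any(keep)) {
    return(new_avalanche_set(
      tibble(avalanche_id = integer(), start_bin = integer(),
             duration = integer(), size = numeric(), heights = list()),
      source = source, bin_ms = bin_ms))
  }
  starts <- starts[keep]; ends <- ends[keep]
  heights <- purrr::map2(starts, ends, function(s, e) as.numeric(counts[s:e]))
  new_avalanche_set(
    tibble(avalanche_id = seq_along(starts), start_bin = starts,
           duration = ends - starts + 1L,
           size = purrr::map_dbl(heights, sum), heights = heights),
    source = source, bin_ms = bin_ms)
}

#' Convert a reflected walk trace into avalanches
#'
#' Zero-to-zero excursions of a non-negative trace become avalanches.
#' Following the coin-flip convention, the duration counts every step in
#' the excursion including the one that returns to zero, so the six-flip
#' run H,H,H,T,T,T (heights 1,2,3,2,1,0) has duration 6 and size 9.  The
#' stored height profile keeps the positive heights only.  A trailing
#' excursion that has not returned to zero is discarded.
#'
#' @param trace A `walk_trace` with non-negative values (reflect first).
#' @return An `avalanche_set` tibble (columns `avalanche_id`, `start_bin`,
#'   `duration`, `size`, `heights`).
#' @export
walk_avalanches <- function(trace) {
  x <- trace$value
  if (any(x < 0))
    abort_critsig("trace has negative values; reflect it first.",
                  "precondition")
  pos <- x > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # an excursion needs a return to zero: the run must not touch the end
  keep <- r$values & ends < length(x)
  if (!any(keep)) {
    return(new_avalanche_set(
      tibble(avalanche_id = integer(), start_bin = integer(),
             duration = integer(), size = numeric(), heights = list()),
      source = "walk"))
  }
  starts <- starts[keep]; ends <- ends[keep]
  heights <- purrr::map2(starts, ends, function(s, e) x[s:e])
  new_avalanche_set(
    tibble(avalanche_id = seq_along(starts), start_bin = starts,
           duration = ends - starts + 2L, # + the returning zero step
           size = purrr::map_dbl(heights, sum), heights = heights),
    source = "walk")
}

#' Exponent relation between avalanche exponents
#'
#' At criticality the size exponent tau, duration exponent alpha and
#' size-duration scaling exponent gamma must interlock:
#' `(alpha - 1) / (tau - 1) = gamma`.  This computes the predicted gamma
#' and its percent discrepancy from the fitted one; e.g. tau = 1.5,
#' alpha = 1.9 predict gamma = 1.8.
#'
#' @param tau Size-distribution exponent (> 1).
#' @param alpha Duration-distribution exponent.
#' @param gamma Fitted size-duration scaling exponent.
#' @return A tibble with `tau`, `alpha`, `gamma`, `gamma_predicted`, and
#'   `relation_error_pct` (= `100 * |predicted - gamma| / gamma`).
#' @export
exponent_relation <- function(tau, alpha, gamma) {
  if (any(tau == 1))
    abort_critsig("tau = 1 makes the relation undefined (division by zero).",
                  "invalid_parameter")
  pred <- (alpha - 1) / (tau - 1)
  tibble(tau = tau, alpha = alpha, gamma = gamma, gamma_predicted = pred,
         relation_error_pct = 100 * abs(pred - gamma) / gamma)
}

#' Mean avalanche size as a function of duration
#'
#' Fits the scaling relation `<S>(T) ~ T^gamma` by regressing the log of
#' the mean size per duration class on log duration.  Only duration
#' classes holding at least `min_count` avalanches enter the fit (sparse
#' tail classes are noisy), and by default the shortest durations are
#' excluded: below `min_duration` the means are dominated by lattice
#' constraints rather than the scaling regime (a two-step excursion has
#' mean size exactly 1, far below any power-law asymptote).
#'
#' @param avs An `avalanche_set` (or any data frame with `duration` and
#'   `size` columns).
#' @param min_count Minimum avalanches per duration class (default 5).
#' @param min_duration Shortest duration admitted to the fit (default 8).
#' @param durations Optional explicit duration range `c(lo, hi)` to fit
#'   over (overrides `min_duration`).
#' @return A `scaling_fit` object; `tidy()` gives the per-duration means,
#'   `glance()` the fitted `gamma`.
#' @export
size_duration_scaling <- function(avs, min_count = 5, min_duration = 8,
                                  durations = NULL) {
  by_t <- dplyr::summarise(dplyr::group_by(as_tibble(avs)[c("duration", "size")],
                                           .data$duration),
                           mean_size = mean(.data$size), n = dplyr::n(),
                           .groups = "drop")
  fit_t <- dplyr::filter(by_t, .data$n >= min_count, .data$duration > 0)
  if (is.null(durations))
    durations <- c(min_duration, Inf)
  fit_t <- dplyr::filter(fit_t, .data$duration >= durations[1],
                         .data$duration <= durations[2])
  if (nrow(fit_t) < 2)
    abort_critsig("need at least two duration classes to fit a slope.",
                  "insufficient_data")
  fit <- lm(log(mean_size) ~ log(duration), data = fit_t)
  structure(list(gamma = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit_range = range(fit_t$duration), by_duration = by_t,
                 n_classes = nrow(fit_t)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<S>(T) ~ T^gamma scaling fit\n  gamma = %.3f over durations [%g, %g] (%d classes)\n",
              x$gamma, x$fit_range[1], x$fit_range[2], x$n_classes))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scaling_fit <- function(x, ...) x$by_duration

#' @exportS3Method generics::glance
glance.scaling_fit <- function(x, ...) {
  tibble(gamma = x$gamma, n_classes = x$n_classes,
         duration_min = x$fit_range[1], duration_max = x$fit_range[2])
}

#' Average avalanche shapes per duration
#'
#' For each requested duration, the element-wise mean of the height
#' profiles of all avalanches with exactly that duration.  Duration
#' classes with fewer than `min_count` members are skipped with a warning.
#'
#' @param avs An `avalanche_set` with a `heights` list-column, or one
#'   produced by [coin_flip_avalanches()] (which carries precomputed shape
#'   sums).
#' @param durations Integer vector of durations to average.
#' @param min_count Minimum avalanches per class (default 20).
#' @return A tibble with columns `duration`, `n`, and a `shape`
#'   list-column of mean height profiles.
#' @export
average_shapes <- function(avs, durations, min_count = 20) {
  pre <- attr(avs, "shapes")
  if (!is.null(pre)) {
    out <- dplyr::filter(pre, .data$duration %in% durations)
  } else {
    if (!"heights" %in% names(avs))
      abort_critsig("avalanche set has no height profiles.", "precondition")
    sub <- dplyr::filter(as_tibble(avs), .data$duration %in% durations)
    out <- dplyr::summarise(
      dplyr::group_by(sub, .data$duration),
      n = dplyr::n(),
      shape = list(Reduce(`+`, .data$heights) / dplyr::n()),
      .groups = "drop")
  }
  missing_t <- setdiff(durations, out$duration[out$n >= min_count])
  if (length(missing_t) > 0)
    warning(sprintf("skipping durations with < %d avalanches: %s",
                    min_count, paste(missing_t, collapse = ", ")))
  dplyr::filter(out, .data$n >= min_count)
}

#' Avalanche shape collapse
#'
#' Rescales each mean avalanche shape onto a common footing: time is
#' normalised to `[0, 1]` by linear interpolation onto a fixed grid, and
#' height is divided by `T^(gamma - 1)`.  Near a critical point all
#' rescaled shapes superimpose onto a single universal scaling function.
#' The collapse error is the variance across durations at each grid point,
#' averaged over the grid and divided by the squared mean rescaled height,
#' so it is invariant to uniform scaling of all shapes.  If `gamma` is not
#' supplied it is chosen to minimise the collapse error over a grid.
#'
#' @param shapes A tibble from [average_shapes()] (columns `duration`,
#'   `shape`), or a named list of profiles (names = durations).
#' @param gamma Rescaling exponent; `NULL` (default) optimises over
#'   `gamma_grid`.
#' @param gamma_grid Candidate exponents (default 1.0 to 2.5 by 0.01).
#' @param n_grid Interpolation grid size (default 50).
#' @return A `collapse_result` with `gamma_used`, `collapse_error`, and the
#'   rescaled shapes; duration-1 profiles are excluded.
#' @export
shape_collapse <- function(shapes, gamma = NULL,
                           gamma_grid = seq(1.0, 2.5, by = 0.01),
                           n_grid = 50) {
  if (!is.data.frame(shapes)) {
    shapes <- tibble(duration = as.numeric(names(shapes)),
                     shape = unname(shapes))
  }
  shapes <- dplyr::filter(shapes, purrr::map_int(.data$shape, length) > 1,
                          .data$duration > 1)
  if (nrow(shapes) < 3)
    abort_critsig("shape collapse needs at least 3 duration classes.",
                  "insufficient_data")
  u <- seq(0, 1, length.out = n_grid)
  interp <- vapply(shapes$shape, function(h) {
    approx(seq(0, 1, length.out = length(h)), h, xout = u)$y
  }, numeric(n_grid)) # n_grid x n_durations

  err_for <- function(g) {
    scl <- sweep(interp, 2, shapes$duration ^ (g - 1), "/")
    mean(apply(scl, 1, var)) / mean(scl) ^ 2
  }
  if (is.null(gamma)) {
    errs <- vapply(gamma_grid, err_for, numeric(1))
    gamma <- gamma_grid[which.min(errs)]
    scan <- tibble(gamma = gamma_grid, collapse_error = errs)
  } else {
    scan <- NULL
  }
  scaled <- sweep(interp, 2, shapes$duration ^ (gamma - 1), "/")
  structure(list(gamma_used = gamma, collapse_error = err_for(gamma),
                 durations = shapes$duration, grid = u,
                 rescaled = scaled, scan = scan),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("shape collapse: gamma = %.2f, collapse error = %.4g (%d durations)\n",
              x$gamma_used, x$collapse_error, length(x$durations)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.collapse_result <- function(x, ...) {
  tibble(gamma_used = x$gamma_used, collapse_error = x$collapse_error,
         n_durations = length(x$durations))
}

#' @exportS3Method generics::tidy
tidy.collapse_result <- function(x, ...) {
  tidyr::expand_grid(duration = x$durations) |>
    dplyr::mutate(curve = purrr::map(.data$duration, function(d) {
      j <- match(d, x$durations)
      tibble(u = x$grid, height = x$rescaled[, j])
    })) |>
    tidyr::unnest("curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
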