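#' Construct a time grid
#'
#' A validated vector of sampling times in hours: strictly increasing,
#' non-negative, at least two points.
#'
#' @param times numeric vector of sampling times (hours).
#' @return numeric vector of class `time_grid`.
#' @export
time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2)
    stop("a time grid needs at least two numeric sampling times")
  times <- as.numeric(times)
  if (any(!is.finite(times)))
    stop("time grid contains non-finite values")
  if (times[1] < 0)
    stop("time grid must start at a non-negative time")
  if (is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing")
  structure(times, class = "time_grid")
}

grid_times <- function(g) {
  if (inherits(g, "time_grid")) return(unclass(g))
  unclass(time_grid(g))
}

#' Construct a measured series on a time grid
#'
#' @param values numeric vector of measurements.
#' @param times sampling times (hours), a numeric vector or [time_grid()].
#' @return list of class `series` with elements `values` and `times`.
#' @export
series <- function(values, times) {
  times <- grid_times(times)
  if (!is.numeric(values) || length(values) != length(times))
    stop("series values and time grid must have equal length")
  if (any(!is.finite(values)))
    stop("series values must be finite")
  structure(list(values = as.numeric(values), times = times),
            class = "series")
}

#' @export
print.series <- function(x, ...) {
  cat(sprintf("<series> %d points on [%g, %g] h\n", length(x$values),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Low-level delay grid constructor
#'
#' Validates an arbitrary vector of candidate delays. Use
#' [build_delay_grid()] for the canonical quadratically spaced grid.
#'
#' @param delays ordered numeric vector of candidate delays (hours),
#'   starting at 0.
#' @return list of class `delay_grid` with `delays`, `n`, `t_max`.
#' @export
delay_grid <- function(delays) {
  if (!is.numeric(delays) || length(delays) < 1)
    stop("delay grid needs at least one delay")
  delays <- as.numeric(delays)
  if (any(!is.finite(delays)) || delays[1] != 0)
    stop("delay grid must be finite and start at 0")
  if (length(delays) > 1 && is.unsorted(delays, strictly = TRUE))
    stop("delay grid must be strictly increasing")
  structure(list(delays = delays, n = length(delays),
                 t_max = delays[length(delays)]),
            class = "delay_grid")
}

#' Build a quadratically spaced delay grid
#'
#' Candidate translation delays tau_j = t_max * (j / (n - 1))^2 for
#' j = 0, ..., n - 1. Spacings grow quadratically, so the grid is dense near
#' zero delay (where most proteins are expected to sit) and coarse near the
#' horizon.
#'
#' @param n number of delays (>= 2).
#' @param t_max horizon in hours (> 0); the largest candidate delay.
#' @return list of class `delay_grid`.
#' @export
#' @examples
#' build_delay_grid(5, 24)$delays
build_delay_grid <- function(n, t_max) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 2 ||
      n != as.integer(n))
    stop("n must be a single integer >= 2")
  if (!is.numeric(t_max) || length(t_max) != 1 || !is.finite(t_max) ||
      t_max <= 0)
    stop("t_max must be a single positive number")
  n <- as.integer(n)
  j <- seq_len(n) - 1L
  delay_grid(t_max * (j / (n - 1))^2)
}

#' @export
print.delay_grid <- function(x, ...) {
  cat(sprintf("<delay_grid> %d delays in [0, %g] h\n", x$n, x$t_max))
  invisible(x)
}

#' Piecewise-linear interpolation with boundary clamping
#'
#' Interpolates a [series()] at arbitrary query times. Queries beyond the
#' last knot return the last knot value and queries before the first knot
#' return the first knot value (no extrapolation), so delayed targets
#' Y(t + tau) beyond the measured horizon stay bounded.
#'
#' @param s a [series()].
#' @param query_times finite numeric vector of query times (hours).
#' @return numeric vector of interpolated values.
#' @export
interpolate_linear <- function(s, query_times) {
  if (!inherits(s, "series"))
    stop("s must be a series")
  if (!is.numeric(query_times) || length(query_times) == 0 ||
      any(!is.finite(query_times)))
    stop("query times must be finite numbers")
  stats::approx(x = s$times, y = s$values, xout = query_times,
                method = "linear", rule = 2, ties = "ordered")$y
}

#' Align protein measurements to an mRNA time grid
#'
#' The paired grid consists of the mRNA time points not exceeding the last
#' protein measurement. Protein values at mRNA-only time points are obtained
#' by linear interpolation; protein measurements beyond the mRNA horizon are
#' dropped (e.g. a 120 h protein point against a 24 h mRNA series).
#'
#' @param mrna_grid mRNA sampling times, numeric or [time_grid()].
#' @param protein a [series()] of protein measurements.
#' @return list with `grid` (the paired [time_grid()]) and `protein`
#'   (a [series()] of protein values on the paired grid).
#' @export
align_timepoints <- function(mrna_grid, protein) {
  mg <- grid_times(mrna_grid)
  if (!inherits(protein, "series"))
    stop("protein must be a series")
  pt <- protein$times
  if (mg[1] > pt[length(pt)] || mg[length(mg)] < pt[1])
    stop("alignment error: mRNA and protein time ranges do not overlap")
  keep <- mg[mg <= pt[length(pt)]]
  if (length(keep) < 2)
    stop("alignment error: fewer than two paired time points")
  list(grid = time_grid(keep),
       protein = series(interpolate_linear(protein, keep), keep))
}
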