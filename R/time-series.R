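#' Uniformly sampled time series
#'
#' Container for a scalar signal sampled on a uniform time grid
#' \eqn{t_k = t_0 + k\,\Delta t}, the form in which pressure and flow
#' records enter the fitting algorithms.  Values are stored in SI units
#' throughout the package (Pa for pressure, m\eqn{^3}/s for flow); use
#' [convert_units()] at the boundaries.
#'
#' @param values numeric (or, for internal filter outputs, complex) vector
#'   of samples; at least two.
#' @param dt sampling interval \eqn{\Delta t} in seconds, strictly positive.
#' @param t0 time of the first sample in seconds.
#' @param unit free-text unit label carried along for printing and file
#'   headers (e.g. `"Pa"`, `"m3/s"`).
#' @return An object of class `time_series`.
#' @examples
#' q <- time_series(sin(seq(0, 2 * pi, length.out = 101)), dt = 0.01,
#'                  unit = "m3/s")
#' head(time_points(q))
#' @export
time_series <- function(values, dt, t0 = 0, unit = "") {
  if (!is.numeric(values) && !is.complex(values))
    stop("`values` must be numeric or complex")
  if (length(values) < 2L)
    stop("a time series needs at least two samples")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite and free of missing entries")
  structure(list(values = as.vector(values), dt = dt, t0 = t0, unit = unit),
            class = "time_series")
}

#' Sampling times of a time series
#'
#' @param ts a [time_series()].
#' @return Numeric vector `t0 + (0:(K)) * dt` matching `ts$values`.
#' @export
time_points <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + ts$dt * (seq_along(ts$values) - 1)
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples, dt = %g s, t0 = %g s%s\n",
              length(x$values), x$dt, x$t0,
              if (nzchar(x$unit)) paste0(" [", x$unit, "]") else ""))
  cat(sprintf("  range: [%.6g, %.6g]\n",
              min(Re(x$values)), max(Re(x$values))))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(t = time_points(x), value = x$values)
}

#' Paired pressure/flow waveforms at an outlet
#'
#' Bundles a pressure and a flow-rate [time_series()] that share the same
#' time grid — the co-located records from which a boundary condition is
#' identified.
#'
#' @param pressure pressure `time_series` (Pa).
#' @param flow flow-rate `time_series` (m\eqn{^3}/s).
#' @return An object of class `hemo_waveforms` with elements `pressure`
#'   and `flow`.
#' @export
hemo_waveforms <- function(pressure, flow) {
  stopifnot(inherits(pressure, "time_series"), inherits(flow, "time_series"))
  if (length(pressure$values) != length(flow$values))
    stop("pressure and flow must have the same length")
  rel <- max(abs(pressure$dt), abs(flow$dt))
  if (abs(pressure$dt - flow$dt) > 1e-12 * rel ||
      abs(pressure$t0 - flow$t0) > 1e-9 * max(1, abs(pressure$t0)))
    stop("pressure and flow must share t0 and dt")
  structure(list(pressure = pressure, flow = flow), class = "hemo_waveforms")
}

#' @export
print.hemo_waveforms <- function(x, ...) {
  cat(sprintf("<hemo_waveforms> %d samples, dt = %g s, span %.4g s\n",
              length(x$pressure$values), x$pressure$dt,
              x$pressure$dt * (length(x$pressure$values) - 1)))
  invisible(x)
}

#' @export
as.data.frame.hemo_waveforms <- function(x, ...) {
  data.frame(t = time_points(x$pressure),
             p = x$pressure$values, q = x$flow$values)
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
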