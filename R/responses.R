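#' Exact Windkessel pressure response (reference oracle)
#'
#' Integrates the RCR differential equation from a vanishing initial state
#' with an adaptive high-order ODE solver.  Using the compliance voltage
#' \eqn{v} as the state,
#' \deqn{C \dot v = q - (v - P_d)/R_2, \qquad p = v + R_1 q,}
#' with \eqn{v(t_0) = 0}, the flow being reconstructed between samples by
#' linear interpolation.  This is the reference ("exact model") response:
#' the distal pressure enters through its exponential start-up transient
#' rather than as an instantaneous step.
#'
#' @param wk a [windkessel()] object.
#' @param q flow-rate [time_series()] (m\eqn{^3}/s).
#' @param rtol,atol solver tolerances; defaults are far tighter than
#'   anything this oracle is used to validate.
#' @return Pressure `time_series` (Pa) on the grid of `q`.
#' @seealso [approx_response()] for the instantaneous-source variant.
#' @export
wk_exact_response <- function(wk, q, rtol = 1e-10, atol = NULL) {
  stopifnot(inherits(wk, "windkessel"), inherits(q, "time_series"))
  tq <- time_points(q)
  qf <- stats::approxfun(tq, q$values, rule = 2)
  scale <- max(abs(wk$Pd), wk$R2 * max(abs(q$values)), 1)
  if (is.null(atol)) atol <- 1e-10 * scale
  deriv <- function(t, y, parms) {
    list((qf(t) - (y[1] - wk$Pd) / wk$R2) / wk$C)
  }
  sol <- deSolve::ode(y = c(v = 0), times = tq, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  p <- sol[, "v"] + wk$R1 * q$values
  time_series(as.numeric(p), dt = q$dt, t0 = q$t0, unit = "Pa")
}

#' Approximate-model pressure response
#'
#' Response of the pole-residue boundary condition under the
#' instantaneous-source convention
#' \eqn{P(s) \approx H(s) Q(s) + P_d/s}: the convolution of the flow with
#' the impulse response of \eqn{H} plus a constant \eqn{P_d} acting from
#' the first sample (\eqn{\theta(0) = 1}).  Computed by exact recursive
#' exponential convolution with piecewise-linear flow reconstruction
#' ([exp_filter()]); differs from [wk_exact_response()] only by the
#' start-up transient \eqn{P_d e^{a t}}, so the two agree in the periodic
#' state.
#'
#' @param m a [pole_residue()] model (or a [windkessel()], converted
#'   internally).
#' @param q flow-rate [time_series()] (m\eqn{^3}/s).
#' @return Pressure `time_series` (Pa) on the grid of `q`.
#' @export
approx_response <- function(m, q) {
  if (inherits(m, "windkessel")) m <- wk_to_pole_residue(m)
  stopifnot(inherits(m, "pole_residue"), inherits(q, "time_series"))
  horizon <- q$dt * (length(q$values) - 1)
  unstable <- Re(m$poles) > 0
  if (any(unstable) && any(Re(m$poles)[unstable] * horizon > 50))
    stop("unstable pole with horizon >> 1/Re(a): response would overflow")
  p <- m$c0 * q$values + m$Pd
  blocks <- pole_blocks(m$poles, m$residues)
  for (b in blocks) {
    f <- exp_filter_num(q$values, b$a, q$dt)
    if (b$type == "real") {
      p <- p + Re(b$c) * Re(f)
    } else {
      # c/(s-a) + conj both: 2*Re(c * f)
      p <- p + 2 * (Re(b$c) * Re(f) - Im(b$c) * Im(f))
    }
  }
  time_series(p, dt = q$dt, t0 = q$t0, unit = "Pa")
}

# Canonical pole blocks: real poles and one representative (Im > 0) per
# conjugate pair, in order of first appearance.  Optionally carries the
# matching residue/coefficient.
pole_blocks <- function(poles, coef = NULL) {
  n <- length(poles)
  scale <- max(Mod(poles), 1)
  used <- logical(n)
  blocks <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    a <- poles[i]
    if (abs(Im(a)) <= 1e-12 * scale) {
      used[i] <- TRUE
      blocks[[length(blocks) + 1L]] <-
        list(type = "real", a = complex(real = Re(a)),
             c = if (is.null(coef)) NULL else coef[i])
    } else {
      j <- which(!used & seq_len(n) != i &
                   Mod(poles - Conj(a)) < 1e-8 * scale)
      if (!length(j)) stop("complex poles must appear in conjugate pairs")
      j <- j[1]
      used[c(i, j)] <- TRUE
      rep_i <- if (Im(a) > 0) i else j
      blocks[[length(blocks) + 1L]] <-
        list(type = "cplx", a = poles[rep_i],
             c = if (is.null(coef)) NULL else coef[rep_i])
    }
  }
  blocks
}

# Expand canonical blocks back to a full conjugate-closed pole/residue set
blocks_to_model <- function(blocks) {
  poles <- complex(0); residues <- complex(0)
  for (b in blocks) {
    if (b$type == "real") {
      poles <- c(poles, b$a); residues <- c(residues, b$c)
    } else {
      poles <- c(poles, b$a, Conj(b$a))
      residues <- c(residues, b$c, Conj(b$c))
    }
  }
  list(poles = poles, residues = residues)
}
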