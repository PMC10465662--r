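#' Realize a fitted model as a time-stepping boundary condition
#'
#' Splits the pole-residue model into real-pole states and conjugate-pair
#' state couples, giving the real-valued state-space system
#' \deqn{\dot x_i = a_{r_i} x_i + q, \qquad
#'       \dot x'_i = \sigma_i x'_i + \omega_i x''_i + 2 q, \quad
#'       \dot x''_i = -\omega_i x'_i + \sigma_i x''_i,}
#' whose output \eqn{p = \sum c_{r_i} x_i + \sum (c'_i x'_i + c''_i x''_i)
#' + c_0 q + P_d} reproduces \eqn{H(s)Q(s) + P_d/s}.  States start at
#' zero.  The forward-Euler step size must satisfy
#' \eqn{|1 + \Delta t\, a_i| < 1} for every pole.
#'
#' @param m a [pole_residue()] model (or [windkessel()], converted).
#' @param dt time-step of the host solver (s).
#' @param allow_unstable permit poles with non-negative real part
#'   (explicit override; off by default).
#' @return An object of class `state_space_bc` holding the gains, the
#'   states, the previous flow sample and the step index — a plain list,
#'   serializable for solver restarts.
#' @seealso [bc_step()], [simulate_bc()]
#' @export
realize_bc <- function(m, dt, allow_unstable = FALSE) {
  if (inherits(m, "windkessel")) m <- wk_to_pole_residue(m)
  stopifnot(inherits(m, "pole_residue"), dt > 0)
  if (!allow_unstable && m$order && any(Re(m$poles) >= 0))
    stop("model has poles with non-negative real part; ",
         "set allow_unstable = TRUE to override")
  if (m$order && any(Re(m$poles) < 0 & Mod(1 + dt * m$poles) >= 1))
    stop("forward-Euler stability violated: need |1 + dt*a| < 1 ",
         "for every pole (reduce dt)")
  blocks <- pole_blocks(m$poles, m$residues)
  re <- blocks[vapply(blocks, function(b) b$type == "real", logical(1))]
  cp <- blocks[vapply(blocks, function(b) b$type == "cplx", logical(1))]
  structure(list(
    a_r = vapply(re, function(b) Re(b$a), numeric(1)),
    c_r = vapply(re, function(b) Re(b$c), numeric(1)),
    sigma = vapply(cp, function(b) Re(b$a), numeric(1)),
    omega = vapply(cp, function(b) Im(b$a), numeric(1)),
    c_re = vapply(cp, function(b) Re(b$c), numeric(1)),
    c_im = vapply(cp, function(b) Im(b$c), numeric(1)),
    c0 = m$c0, Pd = m$Pd, dt = dt,
    x = numeric(length(re)),
    x1 = numeric(length(cp)), x2 = numeric(length(cp)),
    q_prev = 0, k = 0L), class = "state_space_bc")
}

#' Advance the boundary condition by one solver step
#'
#' One forward-Euler update: states are advanced with the *previous* flow
#' sample,
#' \eqn{x_i(t_k) = x_i(t_{k-1}) + \Delta t [a_{r_i} x_i(t_{k-1}) +
#' q(t_{k-1})]} (and the analogous coupled update for conjugate pairs,
#' where the flow enters only the first state with gain 2), after which
#' the outlet pressure is returned with the direct term evaluated at the
#' *current* flow: \eqn{p(t_k) = p_r + p_c + c_0 q(t_k) + P_d}.  This
#' asymmetry mirrors the explicit coupling used by 1D solvers.
#'
#' @param bc a [realize_bc()] object.
#' @param q_k flow-rate sample at the new time level (m\eqn{^3}/s).
#' @return `list(bc = <updated state>, p = <pressure, Pa>)`.
#' @export
bc_step <- function(bc, q_k) {
  stopifnot(inherits(bc, "state_space_bc"))
  if (!is.finite(q_k)) stop("flow sample must be finite")
  dt <- bc$dt; qp <- bc$q_prev
  if (length(bc$x))
    bc$x <- bc$x + dt * (bc$a_r * bc$x + qp)
  if (length(bc$x1)) {
    x1 <- bc$x1; x2 <- bc$x2
    bc$x1 <- x1 + dt * (bc$sigma * x1 + bc$omega * x2 + 2 * qp)
    bc$x2 <- x2 + dt * (-bc$omega * x1 + bc$sigma * x2)
  }
  p <- sum(bc$c_r * bc$x) + sum(bc$c_re * bc$x1 + bc$c_im * bc$x2) +
    bc$c0 * q_k + bc$Pd
  bc$q_prev <- q_k
  bc$k <- bc$k + 1L
  list(bc = bc, p = p)
}

#' Run the boundary condition over a whole flow record
#'
#' Maps a flow series through [bc_step()], returning the pressure the
#' embedded boundary condition would impose — the reference entry point
#' for runtime experiments and the as-deployed counterpart of
#' [approx_response()] (to which it converges at first order in
#' \eqn{\Delta t}).
#'
#' @param m a [pole_residue()] (or [windkessel()]) model.
#' @param q flow-rate [time_series()], or a numeric vector with `dt`.
#' @param dt time-step, required when `q` is a bare vector.
#' @param allow_unstable passed to [realize_bc()].
#' @return Pressure `time_series` on the grid of `q` (or a numeric vector
#'   when `q` is a vector; empty input gives empty output).
#' @export
simulate_bc <- function(m, q, dt = NULL, allow_unstable = FALSE) {
  ts_in <- inherits(q, "time_series")
  qv <- if (ts_in) q$values else q
  if (ts_in) dt <- q$dt
  if (length(qv) == 0L) return(numeric(0))
  if (is.null(dt)) stop("`dt` is required when `q` is a plain vector")
  bc <- realize_bc(m, dt, allow_unstable = allow_unstable)
  n_r <- length(bc$x); n_c <- length(bc$x1)
  K <- length(qv)
  p <- numeric(K)
  # unrolled copy of bc_step (avoids per-step list allocation)
  x <- bc$x; x1 <- bc$x1; x2 <- bc$x2; qp <- 0
  for (k in seq_len(K)) {
    if (n_r) x <- x + dt * (bc$a_r * x + qp)
    if (n_c) {
      t1 <- x1 + dt * (bc$sigma * x1 + bc$omega * x2 + 2 * qp)
      x2 <- x2 + dt * (-bc$omega * x1 + bc$sigma * x2)
      x1 <- t1
    }
    p[k] <- sum(bc$c_r * x) + sum(bc$c_re * x1 + bc$c_im * x2) +
      bc$c0 * qv[k] + bc$Pd
    qp <- qv[k]
  }
  if (ts_in) time_series(p, dt = dt, t0 = q$t0, unit = "Pa") else p
}
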