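#' Causal exponential filter
#'
#' Computes the causal convolution
#' \deqn{z_a(t) = \int_{t_0}^{t} e^{a (t - \tau)}\, z(\tau)\, d\tau}
#' on the sampling grid of `z`, by the recursion
#' \eqn{z_a(t_k) = e^{a \Delta t} z_a(t_{k-1}) + \int_{t_{k-1}}^{t_k}
#' e^{a (t_k - \tau)} z(\tau) d\tau}, where the local integral reconstructs
#' `z` piecewise-linearly (exact quadrature against the exponential
#' kernel).  The first output sample is 0.  This is the workhorse used to
#' form the filtered signal columns of the fitting problem and the
#' model responses.
#'
#' @param z a [time_series()] (real-valued).
#' @param a filter pole (s\eqn{^{-1}}), possibly complex; `a = 0` degenerates
#'   to the running integral of `z`.
#' @return A `time_series` with the filtered values (complex when `a` is
#'   complex).
#' @export
exp_filter <- function(z, a) {
  stopifnot(inherits(z, "time_series"))
  y <- exp_filter_num(Re(z$values), a, z$dt)
  time_series(y, dt = z$dt, t0 = z$t0, unit = z$unit)
}

# numeric-vector core; z real, a possibly complex scalar
exp_filter_num <- function(z, a, dt) {
  K <- length(z)
  if (Mod(a) == 0)
    return(c(0, cumsum(dt * (z[-K] + z[-1]) / 2)))
  if (abs(Re(a)) * dt > 50)
    warning("exponential filter is ill-conditioned: |Re(a)|*dt > 50")
  a <- as.complex(a)
  al <- exp(a * dt)
  # piecewise-linear quadrature weights over one step
  w1 <- (al - 1 - a * dt) / (a^2 * dt)
  w0 <- (al - 1) / a - w1
  u <- c(0, w0 * z[-K] + w1 * z[-1])
  if (Im(a) == 0) {
    y <- stats::filter(Re(u), Re(al), method = "recursive")
    return(as.numeric(y))
  }
  # complex first-order recursion y_k = al*y_{k-1} + u_k rewritten as a
  # real second-order recursion with numerator (1 - conj(al) B):
  # y = (u - conj(al) B u) / (1 - 2 Re(al) B + |al|^2 B^2)
  v <- u - Conj(al) * c(0, u[-K])
  f <- c(2 * Re(al), -Mod(al)^2)
  yr <- as.numeric(stats::filter(Re(v), f, method = "recursive"))
  yi <- as.numeric(stats::filter(Im(v), f, method = "recursive"))
  complex(real = yr, imaginary = yi)
}
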