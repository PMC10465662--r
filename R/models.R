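#' Three-element Windkessel (RCR) parameters
#'
#' The classical order-1 lumped model of the downstream vasculature: a
#' proximal resistance `R1` in series with the parallel combination of a
#' compliance `C` and a distal resistance `R2`, terminated on a constant
#' distal pressure `Pd` (the pressure at which flow to the microcirculation
#' ceases).  The model relates outlet pressure and flow through
#' \deqn{q(1 + R_1/R_2) + C R_1 \dot q = (p - P_d)/R_2 + C \dot p.}
#'
#' @param R1 proximal resistance (Pa s m\eqn{^{-3}}), non-negative.
#' @param R2 distal resistance (Pa s m\eqn{^{-3}}), positive.
#' @param C compliance (m\eqn{^3} Pa\eqn{^{-1}}), positive.
#' @param Pd distal pressure (Pa).
#' @return An object of class `windkessel`.
#' @seealso [wk_to_pole_residue()], [wk_exact_response()]
#' @examples
#' wk <- windkessel(R1 = 0.26e8, R2 = 8.43e8, C = 10.5e-10, Pd = 1580)
#' wk_to_pole_residue(wk)
#' @export
windkessel <- function(R1, R2, C, Pd = 0) {
  vals <- c(R1 = R1, R2 = R2, C = C, Pd = Pd)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("Windkessel parameters must be finite")
  if (R1 < 0) stop("R1 must be non-negative")
  if (R2 <= 0) stop("R2 must be positive")
  if (C <= 0) stop("C must be positive")
  structure(list(R1 = R1, R2 = R2, C = C, Pd = Pd), class = "windkessel")
}

#' @export
print.windkessel <- function(x, ...) {
  cat(sprintf(paste0("<windkessel> R1 = %.4g Pa s/m^3, R2 = %.4g Pa s/m^3, ",
                     "C = %.4g m^3/Pa, Pd = %.4g Pa\n"),
              x$R1, x$R2, x$C, x$Pd))
  cat(sprintf("  time constant R2*C = %.4g s\n", x$R2 * x$C))
  invisible(x)
}

#' Pole-residue (partial-fraction) boundary-condition model
#'
#' A lumped termination of arbitrary order \eqn{n}, represented by its
#' impedance transfer function
#' \deqn{H(s) = c_0 + \sum_{i=1}^{n} \frac{c_i}{s - a_i}}
#' together with a constant distal pressure source `Pd`, so that
#' \eqn{P(s) \approx H(s) Q(s) + P_d/s}.  Complex poles must come in
#' conjugate pairs with conjugate residues; coincident poles are rejected.
#'
#' @param c0 direct (high-frequency) term, Pa s m\eqn{^{-3}}.
#' @param poles complex or numeric vector of poles \eqn{a_i} (s\eqn{^{-1}}).
#' @param residues vector of residues \eqn{c_i}, same length as `poles`.
#' @param Pd distal pressure (Pa).
#' @param require_stable if `TRUE`, reject poles with non-negative real part.
#' @return An object of class `pole_residue` with element `order`.
#' @seealso [eval_H()], [approx_response()], [simulate_bc()]
#' @export
pole_residue <- function(c0, poles, residues, Pd = 0, require_stable = FALSE) {
  poles <- as.complex(poles)
  residues <- as.complex(residues)
  if (length(poles) != length(residues))
    stop("`poles` and `residues` must have the same length")
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0))
    stop("`c0` must be a single finite number")
  if (!is.finite(Pd)) stop("`Pd` must be finite")
  if (length(poles)) {
    if (any(!is.finite(poles)) || any(!is.finite(residues)))
      stop("poles and residues must be finite")
    if (any(Mod(poles) == 0))
      stop("poles must have nonzero magnitude")
    check_conjugate_closure(poles, residues)
    dup <- outer(poles, poles, function(x, y) Mod(x - y)) <
      1e-12 * max(Mod(poles))
    if (any(dup[lower.tri(dup)]))
      stop("coincident poles are not supported")
    if (require_stable && any(Re(poles) >= 0))
      stop("model has poles with non-negative real part")
  }
  structure(list(c0 = c0, poles = poles, residues = residues,
                 Pd = Pd, order = length(poles)),
            class = "pole_residue")
}

# complex poles/residues must appear in conjugate pairs
check_conjugate_closure <- function(poles, residues,
                                    tol = 1e-8) {
  scale_p <- max(Mod(poles), 1)
  scale_c <- max(Mod(residues), 1)
  cplx <- which(abs(Im(poles)) > tol * scale_p)
  used <- logical(length(poles))
  for (i in cplx) {
    if (used[i]) next
    j <- which(!used & seq_along(poles) != i &
                 Mod(poles - Conj(poles[i])) < tol * scale_p)
    if (!length(j))
      stop("complex poles must appear in conjugate pairs")
    j <- j[1]
    if (Mod(residues[j] - Conj(residues[i])) > tol * scale_c)
      stop("residues of a conjugate pole pair must be conjugate")
    used[c(i, j)] <- TRUE
  }
  invisible(TRUE)
}

#' @export
print.pole_residue <- function(x, ...) {
  cat(sprintf("<pole_residue> order %d, c0 = %.4g, Pd = %.4g Pa\n",
              x$order, x$c0, x$Pd))
  if (x$order) {
    for (i in seq_len(x$order))
      cat(sprintf("  a_%d = %.6g%+.6gi   c_%d = %.6g%+.6gi\n",
                  i, Re(x$poles[i]), Im(x$poles[i]),
                  i, Re(x$residues[i]), Im(x$residues[i])))
  }
  invisible(x)
}

#' Convert a Windkessel model to pole-residue form
#'
#' The RCR impedance \eqn{H(s) = R_1 + R_2/(s R_2 C + 1)} is the order-1
#' member of the pole-residue family, with
#' \eqn{a = -1/(R_2 C)}, \eqn{c_1 = 1/C}, \eqn{c_0 = R_1}.
#'
#' @param wk a [windkessel()] object.
#' @return An order-1 [pole_residue()] model carrying `Pd` over.
#' @export
wk_to_pole_residue <- function(wk) {
  stopifnot(inherits(wk, "windkessel"))
  pole_residue(c0 = wk$R1,
               poles = complex(real = -1 / (wk$R2 * wk$C)),
               residues = complex(real = 1 / wk$C),
               Pd = wk$Pd)
}

#' Convert an order-1 pole-residue model back to Windkessel parameters
#'
#' Inverts [wk_to_pole_residue()]: `R1 = c0`, `R2 = -c1/a`, `C = 1/c1`.
#' Only order-1 models with a real negative pole and a real positive
#' residue correspond to a physical RCR circuit.
#'
#' @param m a [pole_residue()] model of order 1.
#' @return A [windkessel()] object.
#' @export
pole_residue_to_wk <- function(m) {
  stopifnot(inherits(m, "pole_residue"))
  if (m$order != 1L)
    stop("only order-1 models are representable as a three-element Windkessel")
  a <- m$poles[1]; c1 <- m$residues[1]
  if (abs(Im(a)) > 1e-10 * Mod(a) || abs(Im(c1)) > 1e-10 * Mod(c1))
    stop("pole and residue must be real for a Windkessel representation")
  a <- Re(a); c1 <- Re(c1)
  if (c1 <= 0) stop("residue must be positive for a Windkessel representation")
  if (a >= 0) stop("pole must be negative for a Windkessel representation")
  windkessel(R1 = m$c0, R2 = -c1 / a, C = 1 / c1, Pd = m$Pd)
}

#' Evaluate the impedance transfer function H(s)
#'
#' Partial-fraction evaluation \eqn{H(s) = c_0 + \sum_i c_i/(s - a_i)}.
#' For conjugate-closed models the value at real `s` is real (a vanishing
#' imaginary part is stripped).
#'
#' @param m a [pole_residue()] model.
#' @param s complex (or numeric) vector of Laplace frequencies.
#' @return Complex vector (numeric when the imaginary part is negligible)
#'   of impedance values, Pa s m\eqn{^{-3}}.
#' @export
eval_H <- function(m, s) {
  stopifnot(inherits(m, "pole_residue"))
  s <- as.complex(s)
  if (m$order &&
      any(outer(s, m$poles, function(x, y) Mod(x - y)) <
            1e-12 * max(Mod(m$poles))))
    stop("H(s) is evaluated at a pole")
  out <- rep(as.complex(m$c0), length(s))
  for (i in seq_len(m$order))
    out <- out + m$residues[i] / (s - m$poles[i])
  if (all(abs(Im(out)) <= 1e-10 * pmax(Mod(out), 1e-300))) out <- Re(out)
  out
}

#' Thevenin equivalent distal-pressure source
#'
#' When the distal pressure source of the RCR circuit is relocated to the
#' port (Thevenin equivalent), it becomes the transient source
#' \eqn{\tilde p_d(t) = P_d (1 - e^{a t})\,\theta(t)} with
#' \eqn{a = -1/(R_2 C)}; it rises to \eqn{P_d} with time constant
#' \eqn{\tau = R_2 C}.  The Heaviside convention is \eqn{\theta(0) = 1}.
#'
#' @param wk a [windkessel()] object.
#' @param t numeric vector of times (s).
#' @return Pressure values (Pa) at `t`.
#' @export
equivalent_source <- function(wk, t) {
  stopifnot(inherits(wk, "windkessel"))
  a <- -1 / (wk$R2 * wk$C)
  ifelse(t >= 0, wk$Pd * (1 - exp(a * t)), 0)
}
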