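#' Configuration for the time-domain vector-fitting engine
#'
#' @param order model order `n` (number of poles), at least 1.
#' @param max_iter maximum number of pole-relocation iterations
#'   \eqn{\nu_{max}} (default 100).
#' @param tol convergence tolerance on the maximum relative pole movement
#'   between successive iterations (poles matched after sorting by real,
#'   then imaginary part).
#' @param band expected frequency band `c(f_min, f_max)` in Hz over which
#'   the initial poles are spread; the default 0.5--25 Hz covers the
#'   cardiac fundamental and its clinically relevant harmonics.
#' @param seed RNG seed for the jitter applied to the initial poles;
#'   `NULL` uses (and advances) the session RNG.
#' @param enforce_stability reflect relocated poles with positive real
#'   part into the left half-plane.  Keep on for models destined for the
#'   time-stepping runtime.
#' @param column_scaling scale the least-squares columns to unit norm
#'   before the SVD (and undo afterwards).  The pressure, flow and step
#'   columns otherwise differ by many orders of magnitude in SI units.
#' @param pd_method distal-pressure estimator: `"ls"` ([pd_from_ls()]),
#'   `"bias"` ([pd_from_bias()]), or `"auto"` which uses `"ls"` when the
#'   record starts from (numerically) vanishing initial conditions and
#'   `"bias"` otherwise.
#' @param pd_window_frac fraction of the record (from the end) used by the
#'   periodic-state bias estimator.
#' @param init_poles optional explicit initial poles (complex,
#'   conjugate-closed), overriding the seeded initialization.
#' @return An object of class `tdvf_config`.
#' @export
tdvf_config <- function(order, max_iter = 100L, tol = 1e-6,
                        band = c(0.5, 25), seed = NULL,
                        enforce_stability = TRUE, column_scaling = TRUE,
                        pd_method = c("auto", "ls", "bias"),
                        pd_window_frac = 0.2, init_poles = NULL) {
  stopifnot(order >= 1, max_iter >= 1, length(band) == 2, band[1] < band[2],
            tol > 0, pd_window_frac > 0, pd_window_frac <= 1)
  structure(list(order = as.integer(order), max_iter = as.integer(max_iter),
                 tol = tol, band = band, seed = seed,
                 enforce_stability = isTRUE(enforce_stability),
                 column_scaling = isTRUE(column_scaling),
                 pd_method = match.arg(pd_method),
                 pd_window_frac = pd_window_frac,
                 init_poles = if (is.null(init_poles)) NULL
                              else as.complex(init_poles)),
            class = "tdvf_config")
}

# Seeded starting poles: conjugate pairs with imaginary parts linearly
# spaced over 2*pi*band, weak damping Re = -|Im|/100, plus one real pole
# at -2*pi*f_min when the order is odd; all jittered uniformly +-10%.
init_poles <- function(cfg) {
  n <- cfg$order
  npair <- n %/% 2L
  nreal <- n %% 2L
  with_local_seed(cfg$seed, {
    poles <- complex(0)
    if (npair > 0) {
      om <- 2 * pi * seq(cfg$band[1], cfg$band[2], length.out = npair)
      om <- om * stats::runif(npair, 0.9, 1.1)
      rep_p <- complex(real = -om / 100, imaginary = om)
      poles <- c(rbind(rep_p, Conj(rep_p)))
    }
    if (nreal)
      poles <- c(poles,
                 complex(real = -2 * pi * cfg$band[1] *
                           stats::runif(1, 0.9, 1.1)))
    poles
  })
}

#' Assemble the homogeneous least-squares problem
#'
#' For trial poles \eqn{\{a_i\}} the fitting condition
#' \eqn{D(s)P(s) \approx N(s)Q(s) + P_d D(s)/s}, written at every sample,
#' becomes the homogeneous system \eqn{A x \approx 0} with
#' \eqn{A = [-\Phi\ \ \Gamma\ \ \Theta]} and \eqn{x = [d; c; b]}.  The
#' blocks hold the raw signal followed by its exponentially filtered
#' versions, one column per pole: \eqn{\Phi} for pressure, \eqn{\Gamma}
#' for flow and \eqn{\Theta} for the unit step (whose raw column is all
#' ones).  For a conjugate pole pair the two complex columns are replaced
#' by the real and imaginary parts of the filtered signal, so `A` stays
#' real; the matching complex coefficient is recovered as
#' \eqn{(x_1 - j x_2)/2} from the two real unknowns.
#'
#' @param w a [hemo_waveforms()] record.
#' @param poles complex vector of distinct, conjugate-closed trial poles.
#' @return An object of class `ls_problem` with elements `Phi`, `Gamma`,
#'   `Theta` and the block structure of the poles.
#' @export
assemble_ls <- function(w, poles) {
  stopifnot(inherits(w, "hemo_waveforms"))
  poles <- as.complex(poles)
  if (any(duplicated(round(cbind(Re(poles), Im(poles)), 12))) ||
      any(outer(poles, poles, function(x, y) Mod(x - y))[
        lower.tri(diag(length(poles)))] < 1e-12 * max(Mod(poles))))
    stop("trial poles must be distinct")
  blocks <- pole_blocks(poles)
  dt <- w$pressure$dt
  K1 <- length(w$pressure$values)
  theta <- rep(1, K1)
  filt_block <- function(z) {
    cols <- vector("list", 0)
    for (b in blocks) {
      f <- exp_filter_num(z, b$a, dt)
      if (b$type == "real") cols <- c(cols, list(Re(f)))
      else cols <- c(cols, list(Re(f), Im(f)))
    }
    do.call(cbind, c(list(z), cols))
  }
  structure(list(Phi = filt_block(w$pressure$values),
                 Gamma = filt_block(w$flow$values),
                 Theta = filt_block(theta),
                 poles = poles, blocks = blocks, dt = dt),
            class = "ls_problem")
}

#' Solve the homogeneous least-squares problem
#'
#' Computes the SVD of \eqn{A = [-\Phi\ \ \Gamma\ \ \Theta]} and takes the
#' right singular vector of the smallest singular value as the non-trivial
#' solution, then rescales it so that the leading denominator coefficient
#' is \eqn{d_0 = 1}.  With column scaling enabled, columns are normalized
#' to unit Euclidean norm before the SVD and the solution is mapped back.
#'
#' @param prob an [assemble_ls()] problem.
#' @param column_scaling logical; see [tdvf_config()].
#' @return An object of class `ls_solution` with coefficient vectors `d`,
#'   `c`, `b` (length `n + 1`, real block coordinates, `d[1]` is
#'   \eqn{d_0 = 1}), the residual \eqn{\|A x\|} of the unit-norm solution,
#'   and the pole block structure.
#' @export
solve_ls <- function(prob, column_scaling = TRUE) {
  stopifnot(inherits(prob, "ls_problem"))
  A <- cbind(-prob$Phi, prob$Gamma, prob$Theta)
  if (nrow(A) <= ncol(A))
    stop("the record is too short for the requested order")
  sc <- rep(1, ncol(A))
  if (column_scaling) {
    sc <- sqrt(colSums(A^2))
    sc[sc == 0] <- 1
    A <- sweep(A, 2, sc, "/")
  }
  dec <- svd(A, nu = 0)
  m <- ncol(A)
  if (m > 1 && (dec$d[m - 1] - dec$d[m]) < 1e-12 * dec$d[1])
    warning("smallest singular value is not unique; solution is degenerate",
            " (tie broken by index)")
  x <- dec$v[, m] / sc
  resid <- dec$d[m] / sqrt(sum(x^2))  # ||A x|| per unit ||x|| in original coords
  npc <- ncol(prob$Phi)
  d <- x[seq_len(npc)]
  cc <- x[npc + seq_len(npc)]
  b <- x[2 * npc + seq_len(npc)]
  if (abs(d[1]) < 1e-12 * sqrt(sum(d^2)))
    stop("denominator constant d0 vanishes; pole relocation is singular")
  structure(list(d = d / d[1], c = cc / d[1], b = b / d[1],
                 d0_raw = d[1], residual = resid, singular_values = dec$d,
                 poles = prob$poles, blocks = prob$blocks),
            class = "ls_solution")
}

# Residue identification with fixed poles (denominator pinned to 1):
# ordinary least squares p ~ [Gamma Theta].  Returns an ls_solution with
# d = e1 so the distal-pressure estimators apply unchanged.
residue_ls <- function(prob, p, column_scaling = TRUE) {
  stopifnot(inherits(prob, "ls_problem"))
  A <- cbind(prob$Gamma, prob$Theta)
  sc <- rep(1, ncol(A))
  if (column_scaling) {
    sc <- sqrt(colSums(A^2))
    sc[sc == 0] <- 1
    A <- sweep(A, 2, sc, "/")
  }
  x <- qr.coef(qr(A), p) / sc
  x[is.na(x)] <- 0
  npc <- ncol(prob$Gamma)
  fitted <- cbind(prob$Gamma, prob$Theta) %*% x
  structure(list(d = c(1, numeric(npc - 1L)), c = x[seq_len(npc)],
                 b = x[npc + seq_len(npc)],
                 residual = sqrt(sum((p - fitted)^2)) /
                   max(sqrt(sum(p^2)), 1e-300),
                 poles = prob$poles, blocks = prob$blocks),
            class = "ls_solution")
}

# real block coordinates -> complex per-block coefficients
block_coef <- function(xvec, blocks) {
  out <- vector("list", length(blocks))
  k <- 1L
  for (i in seq_along(blocks)) {
    if (blocks[[i]]$type == "real") {
      out[[i]] <- complex(real = xvec[k]); k <- k + 1L
    } else {
      out[[i]] <- complex(real = xvec[k] / 2, imaginary = -xvec[k + 1] / 2)
      k <- k + 2L
    }
  }
  out
}

#' Relocate poles to the zeros of the fitted denominator
#'
#' The zeros of \eqn{D(s) = d_0 + \sum_i d_i/(s - a_i)} become the next
#' iteration's poles.  They are computed as the eigenvalues of
#' \eqn{A - B d_0^{-1} C}, the state matrix of the inverse denominator,
#' assembled in real block form: a scalar \eqn{[a]} per real pole, and a
#' rotation block \eqn{[[\sigma, \omega], [-\omega, \sigma]]} with input
#' vector \eqn{[2, 0]^T} per conjugate pair.
#'
#' @param sol an [solve_ls()] solution (supplies the denominator
#'   coefficients).
#' @param poles trial poles used to assemble the problem; defaults to
#'   those stored in `sol`.
#' @param enforce_stability reflect zeros with positive real part across
#'   the imaginary axis.
#' @return Complex vector of relocated poles (conjugate-closed).
#' @export
relocate_poles <- function(sol, poles = NULL, enforce_stability = FALSE) {
  stopifnot(inherits(sol, "ls_solution"))
  blocks <- if (is.null(poles)) sol$blocks else pole_blocks(as.complex(poles))
  n <- sum(vapply(blocks, function(b) if (b$type == "real") 1L else 2L,
                  integer(1)))
  d0 <- sol$d[1]
  if (abs(d0) < 1e-12 * sqrt(sum(sol$d^2)))
    stop("denominator constant d0 vanishes; pole relocation is singular")
  dcoef <- block_coef(sol$d[-1], blocks)
  A <- matrix(0, n, n); B <- numeric(n); Cv <- numeric(n)
  k <- 1L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; dc <- dcoef[[i]]
    if (b$type == "real") {
      A[k, k] <- Re(b$a); B[k] <- 1; Cv[k] <- Re(dc)
      k <- k + 1L
    } else {
      sg <- Re(b$a); om <- Im(b$a)
      A[k, k] <- sg; A[k, k + 1] <- om
      A[k + 1, k] <- -om; A[k + 1, k + 1] <- sg
      B[k] <- 2; B[k + 1] <- 0
      Cv[k] <- Re(dc); Cv[k + 1] <- Im(dc)
      k <- k + 2L
    }
  }
  ev <- eigen(A - outer(B, Cv) / d0, only.values = TRUE)$values
  ev <- as.complex(ev)
  if (enforce_stability) {
    flip <- Re(ev) > 0
    ev[flip] <- complex(real = -Re(ev[flip]), imaginary = Im(ev[flip]))
  }
  ev
}

# maximum relative movement between two pole sets, matched by sorting
pole_movement <- function(old, new) {
  o1 <- order(Re(old), Im(old)); o2 <- order(Re(new), Im(new))
  max(Mod(new[o2] - old[o1]) / pmax(Mod(old[o1]), 1e-300))
}

#' Fit a lumped boundary condition by time-domain vector fitting
#'
#' Iterates assembly ([assemble_ls()]), SVD solve ([solve_ls()]) and pole
#' relocation ([relocate_poles()]) from seeded initial poles until the
#' pole set stabilizes or `max_iter` is reached.  At convergence the
#' denominator degenerates to the constant \eqn{d_0}, so the model is the
#' numerator: poles \eqn{\{a_i\}}, residues \eqn{\{c_i\}} and direct term
#' \eqn{c_0} from a final solve at the converged poles.  The distal
#' pressure is then estimated by [pd_from_ls()] or [pd_from_bias()]
#' according to `cfg$pd_method`.  Records that start mid-cycle (non-zero
#' initial conditions) are handled without modification: the natural
#' response only changes the meaning of the dummy step coefficients, which
#' the `"bias"` estimator does not use.
#'
#' @param w a [hemo_waveforms()] record (SI units).
#' @param cfg a [tdvf_config()].
#' @return An object of class `tdvf_fit` with elements `model`
#'   ([pole_residue()]), `iterations`, `converged`, `pole_history`,
#'   `ls_residual`, `pd_method` and the final `ls_solution`.
#'   Non-convergence is reported through `converged = FALSE`, never as an
#'   error.
#' @examples
#' wk <- windkessel(0.26e8, 8.43e8, 10.5e-10, Pd = 1580)
#' w <- synth_waveforms(inflow_spec(n_cycles = 10, co_lmin = 0.75), wk)
#' fit <- fit_tdvf(w, tdvf_config(order = 1, seed = 1))
#' pole_residue_to_wk(fit$model)
#' @export
fit_tdvf <- function(w, cfg) {
  stopifnot(inherits(w, "hemo_waveforms"), inherits(cfg, "tdvf_config"))
  poles <- if (!is.null(cfg$init_poles)) cfg$init_poles else init_poles(cfg)
  if (length(poles) != cfg$order)
    stop("number of initial poles must equal the model order")
  history <- list(poles)
  resid <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (v in seq_len(cfg$max_iter)) {
    iter <- v
    prob <- assemble_ls(w, poles)
    sol <- solve_ls(prob, cfg$column_scaling)
    newp <- relocate_poles(sol, poles,
                           enforce_stability = cfg$enforce_stability)
    move <- pole_movement(poles, newp)
    resid <- c(resid, sol$residual)
    poles <- newp
    history[[v + 1L]] <- poles
    if (move < cfg$tol) { converged <- TRUE; break }
  }
  # final residue-identification stage at the final pole set: with the
  # poles fixed the denominator is pinned to D = 1, and the residues,
  # direct term and step coefficients follow from an ordinary
  # (non-homogeneous) least squares on p ~ [Gamma Theta].  At convergence
  # this coincides with reading off the numerator of the homogeneous
  # solution; off convergence it still returns the best model with the
  # final poles.
  prob <- assemble_ls(w, poles)
  sol <- residue_ls(prob, w$pressure$values, cfg$column_scaling)
  ccoef <- block_coef(sol$c[-1], sol$blocks)
  blocks <- sol$blocks
  for (i in seq_along(blocks)) blocks[[i]]$c <- ccoef[[i]]
  pr <- blocks_to_model(blocks)
  model <- pole_residue(c0 = sol$c[1], poles = pr$poles,
                        residues = pr$residues, Pd = 0)
  method <- cfg$pd_method
  if (method == "auto") {
    p0 <- abs(w$pressure$values[1]) <= 1e-6 * max(abs(w$pressure$values))
    q0 <- abs(w$flow$values[1]) <= 1e-6 * max(abs(w$flow$values))
    method <- if (p0 && q0) "ls" else "bias"
  }
  model$Pd <- if (method == "ls") pd_from_ls(sol)
              else pd_from_bias(w, model, frac = cfg$pd_window_frac)
  structure(list(model = model, iterations = iter, converged = converged,
                 pole_history = history, ls_residual = resid,
                 pd_method = method, solution = sol, config = cfg),
            class = "tdvf_fit")
}

#' @export
print.tdvf_fit <- function(x, ...) {
  cat(sprintf("<tdvf_fit> order %d, %d iteration(s), %s (Pd via '%s')\n",
              x$model$order, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$pd_method))
  print(x$model)
  invisible(x)
}
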