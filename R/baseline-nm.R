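#' Configuration for the Nelder-Mead Windkessel baseline
#'
#' @param init optional [windkessel()] starting point; default is a
#'   Thevenin-style guess from the data (total resistance from the DC
#'   pressure/flow ratio, distal pressure near the diastolic minimum, time
#'   constant of the order of one second).
#' @param scales optional positive normalization scales for
#'   `(R1, R2, C, Pd)`; default is the magnitude of the initial guess.
#'   The simplex search runs on the normalized parameters.
#' @param max_eval maximum number of objective evaluations per start.
#' @param tol relative convergence tolerance of the simplex.
#' @param restarts number of simplex restarts from the previous optimum
#'   (the simplex collapses and benefits from re-inflation).
#' @return An object of class `nm_config`.
#' @export
nm_config <- function(init = NULL, scales = NULL, max_eval = 4000L,
                      tol = 1e-12, restarts = 3L) {
  if (!is.null(init)) stopifnot(inherits(init, "windkessel"))
  if (!is.null(scales)) stopifnot(length(scales) == 4, all(scales > 0))
  structure(list(init = init, scales = scales,
                 max_eval = as.integer(max_eval), tol = tol,
                 restarts = as.integer(restarts)),
            class = "nm_config")
}

#' Windkessel fitting objective
#'
#' Squared 2-norm, summed over all samples, of the residual between the
#' measured pressure and the RCR response written with recursive
#' exponential convolutions under the instantaneous distal-source
#' convention:
#' \deqn{\Big\| p(t) - R_1 q(t) - \tfrac{1}{C}\!\int_0^t
#'   e^{-(t-\tau)/(R_2 C)} q(\tau)\, d\tau - P_d \Big\|^2 .}
#' The objective vanishes (to quadrature accuracy) when the data were
#' generated by exactly these parameters from a vanishing initial state.
#'
#' @param wk trial [windkessel()] parameters.
#' @param w a [hemo_waveforms()] record.
#' @return Scalar cost (Pa\eqn{^2}).
#' @export
wk_objective <- function(wk, w) {
  stopifnot(inherits(wk, "windkessel"), inherits(w, "hemo_waveforms"))
  a <- -1 / (wk$R2 * wk$C)
  qf <- Re(exp_filter_num(w$flow$values, a, w$flow$dt))
  r <- w$pressure$values -
    (wk$R1 * w$flow$values + qf / wk$C + wk$Pd)
  sum(r^2)
}

# data-driven starting point for the simplex
thevenin_guess <- function(w) {
  p <- w$pressure$values; q <- w$flow$values
  Pd0 <- 0.8 * min(p)
  qbar <- mean(q)
  Rtot <- max((mean(p) - Pd0) / max(qbar, 1e-300), 1e-300)
  R1 <- 0.15 * Rtot
  R2 <- Rtot - R1
  windkessel(R1 = R1, R2 = R2, C = 1 / R2, Pd = Pd0)  # tau ~ 1 s
}

#' Fit a three-element Windkessel by Nelder-Mead simplex search
#'
#' Minimizes [wk_objective()] over `(R1, R2, C, Pd)`, normalized by
#' per-parameter scales for faster convergence, using the Nelder-Mead
#' simplex method ([stats::optim()]).  Non-physical trial points
#' (`R2 <= 0`, `C <= 0`, `R1 < 0`) are rejected by penalty.  This is the
#' conventional baseline against which the vector-fitting estimates can
#' be cross-validated; unlike vector fitting it does not generalize
#' beyond order 1.
#'
#' @param w a [hemo_waveforms()] record (SI units).
#' @param cfg an [nm_config()].
#' @return A [windkessel()] object with attributes `cost` (final
#'   objective), `evaluations` and `converged`; on non-convergence the
#'   best point found so far is returned with `converged = FALSE`.
#' @export
fit_nelder_mead <- function(w, cfg = nm_config()) {
  stopifnot(inherits(w, "hemo_waveforms"), inherits(cfg, "nm_config"))
  init <- if (is.null(cfg$init)) thevenin_guess(w) else cfg$init
  p0 <- c(init$R1, init$R2, init$C, init$Pd)
  scales <- if (is.null(cfg$scales)) pmax(abs(p0), 1e-300) else cfg$scales
  fn <- function(th) {
    par <- th * scales
    if (par[2] <= 0 || par[3] <= 0 || par[1] < 0) return(1e100)
    wk_objective(windkessel(par[1], par[2], par[3], par[4]), w)
  }
  th <- p0 / scales
  opt <- NULL
  nev <- 0L
  for (r in seq_len(max(1L, cfg$restarts))) {
    prev <- if (is.null(opt)) Inf else opt$value
    opt <- stats::optim(th, fn, method = "Nelder-Mead",
                        control = list(maxit = cfg$max_eval,
                                       reltol = cfg$tol))
    th <- opt$par
    nev <- nev + opt$counts[["function"]]
    if (is.finite(prev) && prev - opt$value <= cfg$tol * (abs(prev) + 1e-300))
      break
  }
  par <- opt$par * scales
  out <- windkessel(par[1], par[2], par[3], par[4])
  attr(out, "cost") <- opt$value
  attr(out, "evaluations") <- nev
  attr(out, "converged") <- opt$convergence == 0
  out
}
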