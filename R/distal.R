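#' Distal pressure from the least-squares dummy variables
#'
#' The homogeneous fit carries dummy unknowns \eqn{b_i = P_d d_i} (valid
#' when the record starts from vanishing initial conditions).  The best
#' common factor is the projection
#' \deqn{P_d = \frac{d^T b}{\|d\|^2}.}
#' With non-zero initial conditions the dummies become
#' \eqn{b_i = P_d d_i + r_i} (the natural-response residues leak in) and
#' this estimator is biased; use [pd_from_bias()] instead.
#'
#' @param sol an [solve_ls()] solution.
#' @return Distal pressure estimate (Pa).
#' @export
pd_from_ls <- function(sol) {
  stopifnot(inherits(sol, "ls_solution"))
  nd2 <- sum(sol$d^2)
  if (nd2 == 0) stop("denominator coefficient vector is zero")
  sum(sol$d * sol$b) / nd2
}

#' Distal pressure as the periodic-state bias
#'
#' In the periodic state the instantaneous-source relation
#' \eqn{P_d/s \approx P(s) - H(s) Q(s)} is exact, so \eqn{P_d} is the mean
#' offset between the measured pressure and the model response computed
#' without the distal source:
#' \deqn{P_d = \frac{1}{K - c + 1} \sum_{k=c}^{K}
#'       \left[p(t_k) - p_m(t_k)\right],}
#' with \eqn{p_m} from [approx_response()] at \eqn{P_d = 0}.  The window
#' must lie in the periodic state, i.e. start after the distal-source and
#' natural-response transients have extinguished.
#'
#' @param w a [hemo_waveforms()] record.
#' @param m fitted [pole_residue()] model (its `Pd` is ignored).
#' @param t_c start time of the periodic-state window (s); default is the
#'   start of the last `frac` of the record.
#' @param frac fraction of the record used when `t_c` is not given.
#' @return Distal pressure estimate (Pa).
#' @export
pd_from_bias <- function(w, m, t_c = NULL, frac = 0.2) {
  stopifnot(inherits(w, "hemo_waveforms"), inherits(m, "pole_residue"))
  tt <- time_points(w$pressure)
  if (is.null(t_c)) t_c <- tt[1] + (1 - frac) * (tt[length(tt)] - tt[1])
  idx <- which(tt >= t_c)
  if (!length(idx)) stop("periodic-state window is empty")
  m0 <- m; m0$Pd <- 0
  pm <- approx_response(m0, w$flow)
  mean(w$pressure$values[idx] - pm$values[idx])
}
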