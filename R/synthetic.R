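#' Pulsatile inflow specification
#'
#' Operating point and discretization for the synthetic inflow generator:
#' a half-sine systolic pulse train (zero flow in diastole) scaled so the
#' mean flow matches the prescribed per-outlet output.  Defaults are a
#' resting adult operating point (heart rate 66.9 bpm) with a branch flow
#' of 0.75 l/min, which yields physiological pressures at a large-artery
#' outlet of total resistance ~9e8 Pa s/m^3.
#'
#' @param hr_bpm heart rate (beats per minute).
#' @param co_lmin mean flow through the outlet (l/min).  For an aortic
#'   root this is the cardiac output (e.g. 5.2 l/min at rest); for a
#'   branch outlet it is the fraction of cardiac output that vessel
#'   carries.
#' @param systole_frac fraction of the cycle occupied by systole.
#' @param n_cycles number of cardiac cycles to generate.
#' @param dt sampling interval (s).
#' @param ramp_cycles smooth amplitude ramp over the first cycles (0
#'   disables; the waveform always starts at zero flow).
#' @return An object of class `inflow_spec`.
#' @export
inflow_spec <- function(hr_bpm = 66.9, co_lmin = 0.75, systole_frac = 0.35,
                        n_cycles = 20L, dt = 1e-3, ramp_cycles = 0) {
  stopifnot(hr_bpm > 0, co_lmin > 0, systole_frac > 0, systole_frac < 1,
            n_cycles >= 1, dt > 0, ramp_cycles >= 0)
  period <- 60 / hr_bpm
  if (dt > systole_frac * period / 10)
    stop("dt too coarse: need at least 10 samples per systole")
  structure(list(hr_bpm = hr_bpm, co_lmin = co_lmin,
                 systole_frac = systole_frac, n_cycles = n_cycles,
                 dt = dt, ramp_cycles = ramp_cycles, period = period),
            class = "inflow_spec")
}

#' Generate a pulsatile inflow waveform
#'
#' Half-sine systolic pulses: within each cycle of period \eqn{T},
#' \eqn{q(t) = A \sin(\pi t / T_{sys})} for \eqn{t < T_{sys}} and zero in
#' diastole, with \eqn{A} chosen so the cycle-mean flow equals the
#' prescribed `co_lmin` (in SI, m\eqn{^3}/s).  A smooth half-cosine
#' amplitude ramp can be applied over the first `ramp_cycles` cycles.
#'
#' @param spec an [inflow_spec()].
#' @return Flow-rate [time_series()] (m\eqn{^3}/s) starting at `t = 0`.
#' @export
make_inflow <- function(spec) {
  stopifnot(inherits(spec, "inflow_spec"))
  T <- spec$period
  Tsys <- spec$systole_frac * T
  co_si <- spec$co_lmin / 6e4
  A <- co_si * pi * T / (2 * Tsys)
  K <- round(spec$n_cycles * T / spec$dt)
  t <- spec$dt * (0:K)
  tc <- t %% T
  q <- ifelse(tc < Tsys, A * sin(pi * tc / Tsys), 0)
  if (spec$ramp_cycles > 0) {
    Tr <- spec$ramp_cycles * T
    w <- ifelse(t < Tr, 0.5 * (1 - cos(pi * t / Tr)), 1)
    q <- q * w
  }
  time_series(q, dt = spec$dt, t0 = 0, unit = "m3/s")
}

#' Synthesize a pressure/flow dataset from a known termination
#'
#' Drives a known boundary-condition model with the synthetic inflow and
#' records the resulting pressure, producing a fully specified test
#' dataset whose ground truth travels with it (attribute `truth`).
#' The `"approximate"` variant applies the distal pressure as an
#' instantaneous step ([approx_response()]); the `"exact"` variant (3WK
#' only) integrates the Windkessel ODE from a vanishing initial state
#' ([wk_exact_response()]), so the distal source rises exponentially.
#'
#' @param spec an [inflow_spec()].
#' @param model a [windkessel()] or [pole_residue()] ground-truth model.
#' @param variant `"approximate"` or `"exact"`.
#' @param noise optional [noise_spec()] applied per its `applies_to`
#'   field.
#' @return A [hemo_waveforms()] object with attribute `truth = list(model,
#'   spec, variant)` (and `noise_std` when noise is added).
#' @export
synth_waveforms <- function(spec, model,
                            variant = c("approximate", "exact"),
                            noise = NULL) {
  variant <- match.arg(variant)
  q <- make_inflow(spec)
  p <- if (variant == "exact") {
    if (!inherits(model, "windkessel"))
      stop("the exact (ODE) variant requires a Windkessel model")
    wk_exact_response(model, q)
  } else {
    approx_response(model, q)
  }
  noise_std <- NULL
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (noise$applies_to %in% c("pressure", "both")) {
      np <- add_noise(p, noise)
      p <- np$series
      noise_std <- c(pressure = np$noise_std)
      # decorrelate the flow noise stream from the pressure one
      if (!is.null(noise$seed)) noise <- noise_respec(noise, noise$seed + 1L)
    }
    if (noise$applies_to %in% c("flow", "both")) {
      nq <- add_noise(q, noise)
      q <- nq$series
      noise_std <- c(noise_std, flow = nq$noise_std)
    }
  }
  w <- hemo_waveforms(p, q)
  attr(w, "truth") <- list(model = model, spec = spec, variant = variant,
                           noise_std = noise_std)
  w
}

noise_respec <- function(spec, seed) {
  spec$seed <- seed
  spec
}

#' Reference order-8 termination for high-order experiments
#'
#' A fixed, stable order-8 pole-residue termination used as ground truth
#' in the order-sweep experiments.  It has the structure of a realistic
#' vascular input impedance: an RCR-like backbone (a slow real pole
#' carrying most of the DC resistance, plus a faster real pole) corrected
#' by three damped conjugate pairs at 3.5, 7 and 12 Hz — inside the band
#' excited by the pulsatile inflow's harmonics — with residues aligned as
#' \eqn{c = -k a} (positive gain \eqn{k}) so every pair adds a positive
#' DC resistance.  Total DC impedance \eqn{H(0) \approx 9\times 10^8}
#' Pa s m\eqn{^{-3}} and distal pressure 1.5 kPa give physiological
#' pressures at a large-artery outlet, but with dynamics no order-1
#' model can reproduce.
#'
#' @return A [pole_residue()] model of order 8.
#' @export
demo_high_order_model <- function() {
  f <- c(3.5, 7, 12)
  sg <- -c(6, 12, 22)
  k <- c(0.05, 0.03, 0.02) * 1e8
  a <- complex(real = sg, imaginary = 2 * pi * f)
  cc <- -k * a
  pole_residue(c0 = 0.26e8,
               poles = c(complex(real = -1.1299), complex(real = -15),
                         c(rbind(a, Conj(a)))),
               residues = c(complex(real = 9.524e8), complex(real = 1.5e8),
                            c(rbind(cc, Conj(cc)))),
               Pd = 1500)
}

#' Additive white-noise specification
#'
#' @param snr_db signal-to-noise ratio in dB, \eqn{10 \log_{10}} of signal
#'   power over noise power.
#' @param seed RNG seed for reproducible realizations (`NULL` uses the
#'   session RNG).
#' @param applies_to which channel(s) of a dataset the noise corrupts.
#' @param reference `"ac"` measures signal power on the mean-removed
#'   signal (default); `"total"` uses the raw power.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db, seed = NULL,
                       applies_to = c("both", "pressure", "flow"),
                       reference = c("ac", "total")) {
  stopifnot(is.finite(snr_db))
  structure(list(snr_db = snr_db, seed = seed,
                 applies_to = match.arg(applies_to),
                 reference = match.arg(reference)),
            class = "noise_spec")
}

#' Corrupt a signal with white Gaussian noise at a prescribed SNR
#'
#' The noise standard deviation is
#' \eqn{\sigma = \mathrm{RMS}(z) \cdot 10^{-\mathrm{SNR}/20}}, with the
#' RMS taken over the mean-removed signal under the default `"ac"`
#' reference convention.
#'
#' @param z a [time_series()].
#' @param spec a [noise_spec()].
#' @return `list(series = <noisy time_series>, noise_std = <sd used>)`.
#' @export
add_noise <- function(z, spec) {
  stopifnot(inherits(z, "time_series"), inherits(spec, "noise_spec"))
  v <- Re(z$values)
  pw <- if (spec$reference == "ac") mean((v - mean(v))^2) else mean(v^2)
  if (pw == 0)
    stop(if (spec$reference == "ac") "signal has zero AC power"
         else "signal has zero power")
  sd <- sqrt(pw) * 10^(-spec$snr_db / 20)
  noise <- with_local_seed(spec$seed, stats::rnorm(length(v), 0, sd))
  out <- z
  out$values <- v + noise
  list(series = out, noise_std = sd)
}
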