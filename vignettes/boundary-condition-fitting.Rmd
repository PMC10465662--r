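---
title: "Estimating lumped outflow boundary conditions by time-domain vector fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lumped outflow boundary conditions by time-domain vector fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdvfbc)
```

## The modelling problem

A truncated haemodynamic model needs, at every outlet, a relation
between pressure $p(t)$ and flow rate $q(t)$ that stands in for the
downstream vasculature.  The classical three-element Windkessel (RCR)
circuit imposes

$$q\left(1 + \frac{R_1}{R_2}\right) + C R_1 \dot q
  = \frac{p - P_d}{R_2} + C \dot p,$$

with proximal resistance $R_1$, distal resistance $R_2$, compliance $C$
and a constant distal pressure $P_d$ below which flow to the
microcirculation ceases.  In the Laplace domain this reads
$P(s) = H(s)Q(s) + H_d(s)P_d/s$ with

$$H(s) = R_1 + \frac{R_2}{s R_2 C + 1}
       = c_0 + \frac{c_1}{s-a}, \qquad
  a = -\frac{1}{R_2 C},\; c_1 = \frac{1}{C},\; c_0 = R_1 .$$

Two observations make the generalization to arbitrary order natural.
First, by Thevenin's theorem the distal source can be relocated to the
port, where it becomes the transient $\tilde p_d(t) = P_d(1 -
e^{at})\theta(t)$ ([`equivalent_source()`]) with time constant $R_2 C$.
Second, simulations are run to the pulsatile *periodic state*, and only
that regime is of clinical interest; replacing the transient source by
the constant $P_d$ — i.e. approximating

$$P(s) \approx H(s) Q(s) + \frac{P_d}{s}$$

— changes nothing once the start-up transient has died out.  Under this
convention the termination is fully described by an impedance in
pole-residue form,

$$H(s) = c_0 + \sum_{i=1}^{n} \frac{c_i}{s - a_i},$$

of arbitrary order $n$, with complex poles in conjugate pairs.  The
package keeps the exact RCR response ([`wk_exact_response()`], adaptive
`deSolve` integration at tolerance $10^{-10}$) and the
instantaneous-source response ([`approx_response()`], exact recursive
exponential convolution) as two independent oracles; their difference is
analytically $P_d e^{at}$, and the test suite verifies that they agree
on the final cycle to better than 0.1% once the horizon exceeds ten time
constants.

## The identification algorithm

`fit_tdvf()` estimates $\{a_i\}$, $\{c_i\}$, $c_0$ and $P_d$ from
sampled records $p(t_k), q(t_k)$, $k = 0..K$, on a uniform grid.  The
transfer function is parameterized as a ratio $H = N/D$ of two rational
functions sharing a common *trial* pole set,

$$N(s) = c_0 + \sum \frac{c_i}{s-a_i}, \qquad
  D(s) = d_0 + \sum \frac{d_i}{s-a_i},$$

and the fitting condition $D P \approx N Q + P_d D / s$ becomes, after
an inverse Laplace transform, a relation between the signals and their
exponentially filtered versions

$$z_i(t) = \int_0^t e^{a_i (t-\tau)} z(\tau)\, d\tau,$$

computed by [`exp_filter()`].  Writing it at every sample gives the
homogeneous least-squares problem $A x \approx 0$ with
$A = [-\Phi\ \Gamma\ \Theta]$, where $\Phi$, $\Gamma$, $\Theta$ collect
the raw and filtered pressure, flow, and unit step, and
$x = [d; c; b]$ stacks the denominator, numerator and *dummy* step
coefficients $b_i = P_d d_i$ that keep the problem linear despite the
unknown distal pressure.  The solution is the right singular vector of
the smallest singular value ([`solve_ls()`]), rescaled to $d_0 = 1$.

The trial poles are then *relocated* to the zeros of the fitted
denominator — computed as the eigenvalues of $A - B d_0^{-1} C$ from the
real block realization of $D(s)$ ([`relocate_poles()`]) — and the
process repeats until the pole set stabilizes or `max_iter` (default
100) is reached.  At convergence $D$ degenerates to a constant, so the
model is the numerator evaluated at the converged poles.

Three aspects are implementation choices the algorithm statement leaves
open, and are worth recording:

* **Final residue stage.**  After the last relocation the residues are
  re-estimated by an ordinary least squares on
  $p \approx [\,\Gamma\ \Theta\,][c; b]$ with the poles fixed and
  $D \equiv 1$.  At convergence this coincides with reading off the
  numerator of the homogeneous solution; when the relocation does not
  converge (under-modelling can produce a two-point limit cycle — order
  2 on the order-8 demo data is a reproducible example) it still returns
  the best model with the final poles instead of an inconsistent
  numerator/denominator pair.
* **Real arithmetic for conjugate pairs.**  For a pair
  $(a, \bar a)$ the two complex columns are replaced by the real and
  imaginary parts of the filtered signal, and the two real unknowns
  $(x_1, x_2)$ map back to the complex coefficient $(x_1 - j x_2)/2$, so
  $A$ and $x$ stay real throughout.
* **Column scaling.**  Pressure (Pa), flow (m³/s) and step
  (dimensionless) columns differ by ~13 orders of magnitude in SI units;
  columns are normalized to unit norm before the SVD and the solution is
  mapped back.  The fitted $H$ and $P_d$ are invariant to this and to
  the $d_0 = 1$ normalization.

### Initial poles and convergence control

The iteration needs a starting pole set spread over the band the data
actually excite.  The default band is 0.5–25 Hz — the cardiac
fundamental (~1.1 Hz at rest) and its clinically relevant harmonics.
`init_poles` places $\lfloor n/2 \rfloor$ weakly damped conjugate pairs
with imaginary parts linearly spaced over $2\pi\,[f_{\min}, f_{\max}]$,
real parts $-\omega/100$ (standard vector-fitting practice: poles too
damped smear the filters, poles on the axis ill-condition them), plus
one real pole at $-2\pi f_{\min}$ for odd $n$, all jittered ±10% under
`seed`.  Convergence is declared when the maximum relative pole movement
(poles matched after sorting by real, then imaginary part) drops below
`tol = 1e-6`; the least-squares residual history is also stored, but
pole movement is the criterion because it is what the relocation fixed
point is defined by.  Non-convergence is reported as `converged =
FALSE`, never as an error.  Relocated poles that cross into the right
half-plane are reflected across the imaginary axis when
`enforce_stability` is on (the default): a boundary condition destined
for a time-stepping solver must be stable, and reflection preserves the
magnitude response.

### Distal pressure

Two estimators are provided.  `pd_from_ls()` exploits
$b_i = P_d d_i$: the projection $P_d = d^T b / \lVert d \rVert^2$.
`pd_from_bias()` uses the periodic state, where $P_d/s = P - HQ$ is
exact: the mean of $p - p_m$ over a late window, with $p_m$ the model
response at $P_d = 0$; the default window is the last 20% of the
record, which for the default 20-cycle records starts well past ten
time constants of every model considered here.

When the record starts mid-cycle ($p(t_0), q(t_0) \neq 0$) the pressure
contains a natural-response component with the same poles as $H$; its
parameterization is absorbed entirely by the dummy coefficients, which
become $b_i = P_d d_i + r_i$.  The estimation of $c$, $d$ — hence $H$ —
is therefore *unchanged*, and the test suite verifies that a mid-cycle
truncation moves the fitted impedance by under 0.5% across the band.
Only the premise of `pd_from_ls()` breaks: the suite asserts that on
truncated records the projection estimator is visibly biased while the
bias estimator still recovers the generator $P_d$ to 1%.  `fit_tdvf()`
selects the estimator automatically: `"ls"` when the first samples of
both channels are numerically zero, `"bias"` otherwise (the choice is
recorded in the fit object).

## The runtime

`realize_bc()` turns a fitted model into the real state-space system

$$\dot x_i = a_{r_i} x_i + q, \qquad
  \begin{cases}
  \dot x'_i = \sigma_i x'_i + \omega_i x''_i + 2q\\
  \dot x''_i = -\omega_i x'_i + \sigma_i x''_i
  \end{cases}$$

with output $p = \sum c_{r_i} x_i + \sum (c'_i x'_i + c''_i x''_i) +
c_0 q + P_d$.  `bc_step()` advances it by one forward-Euler step — the
scheme explicit haemodynamic solvers use for their lumped outlets — with
a deliberate asymmetry: states advance with the *previous* flow sample
while the direct term uses the *current* one, mirroring how an explicit
1D scheme couples to its boundary at the new time level.  The flow
enters a conjugate-pair block only through $x'$, with gain 2.  These
conventions are kept bit-faithful rather than "improved", because the
runtime's purpose is to reproduce what a solver embedding the model
would compute; the convolution oracle is available when accuracy is the
point.  `realize_bc()` refuses step sizes violating
$|1 + \Delta t\, a_i| < 1$ for any pole, and unstable models require an
explicit override.  First-order convergence of the runtime to
`approx_response()` is asserted by Richardson halving in the tests.

## The synthetic generator

No public dataset pairs outlet pressure and flow with a known
ground-truth termination, so the generator *is* the experiment
definition.  `make_inflow()` produces a half-sine systolic pulse train
(systole occupying 35% of the cycle by default, zero diastolic flow)
scaled so the mean flow equals the prescribed output; `synth_waveforms()`
drives a known model with it and attaches the ground truth to the
dataset.  The default operating point is a resting heart rate of 66.9
bpm.  The default *branch* flow is 0.75 l/min: study-scale experiments
use a brachiocephalic-territory parameter set with total resistance
$\approx 8.7\times10^8$ Pa s m⁻³, and 0.75 l/min is the flow such a
termination draws at a physiological mean pressure (~93 mmHg); a whole
cardiac output of ~5 l/min belongs to an aortic root, not to one branch.
`add_noise()` injects white Gaussian noise at a prescribed SNR.  SNR is
referenced to the *mean-removed* (AC) signal power by default — a
pressure waveform rides on a large DC offset, and referencing total
power would make "20 dB" mean noise larger than the entire pulse
pressure; the total-power convention remains selectable.

What the generator does **not** emulate: the skewed, notched shape of a
real aortic flow wave (only its pulsatility and harmonic richness),
wave reflections between measurement site and termination, beat-to-beat
variability, baroreflex adaptation, or correlated measurement error.
Passing tests therefore demonstrate correctness of the identification
machinery under the stated linear-time-invariant conditions, not
robustness to physiological non-stationarity.

The order-sweep experiments use `demo_high_order_model()`, a fixed
order-8 termination built like a realistic vascular input impedance: an
RCR-like backbone (slow real pole at $-1.13$ s⁻¹ carrying most of the
DC resistance, plus a faster real pole) corrected by three damped
conjugate pairs at 3.5, 7 and 12 Hz.  Its parameters are part of the
experiment definition and are not adjusted per run.

## Study-scale experiments and their conventions

The end-to-end checks in `tests/testthat/test-acceptance.R` run at the
scale the package documents as its study conditions: 20 cardiac cycles
sampled at 1 kHz (≈ 18 000 samples), ten noise realizations per SNR
level.  Two conventions deserve justification:

* **Noise study.**  The reconstruction error is measured on the
  boundary condition *as deployed* — the forward-Euler runtime at the
  acquisition rate — against the noiseless reference.  A deployed model
  carries a discretization floor (≈ 0.07% at 1 ms for the RCR time
  constants used), so the error is flat from 100 dB down to 40 dB SNR
  and rises only at 20 dB, where it stays below 1%.  Measuring the
  continuous-time model response instead would show the error falling
  indefinitely with noise — true, but not what a solver user
  experiences.
* **Order sweep.**  Fit quality across orders is compared on the
  *a-priori* model response (`approx_response()`), i.e. the model alone
  against the data it was fitted to, over the final cycle; the error
  drops by far more than an order of magnitude from order 1 to order 8
  on the order-8 ground truth.

## Numerical choices and degenerate inputs

* The exponential filter reconstructs its input piecewise-linearly and
  integrates it exactly against the kernel; zero-order-hold quadrature
  measurably biases the recovered compliance at 1 ms sampling.  The
  recursion for a complex pole is evaluated as a real second-order
  recursion via `stats::filter` (numerator $1 - \bar\alpha B$,
  denominator $1 - 2\,\mathrm{Re}(\alpha) B + |\alpha|^2 B^2$,
  $\alpha = e^{a\Delta t}$).  `a = 0` degenerates to the running
  trapezoidal integral; $|\mathrm{Re}(a)|\,\Delta t > 50$ warns of an
  ill-conditioned filter.
* The Heaviside convention is $\theta(0) = 1$: the distal source acts
  from the first sample.
* Coincident poles are rejected rather than extended to Jordan blocks;
  the model family is restricted to simple poles, which relocation
  generically produces anyway.
* A non-unique smallest singular value triggers a degeneracy warning
  (tie broken by index); this occurs benignly when the requested order
  exceeds the order of the underlying data.
* All internal units are strict SI; `convert_units()` holds the single
  mmHg constant (133.322387415 Pa).  Model JSON is written at 17
  significant digits so round trips are bit-stable.
* The Nelder–Mead baseline minimizes the sum of squared residuals of
  the recursive-convolution RCR response under the same
  instantaneous-source convention as the fitter, so its minimum is the
  generating model on self-generated data — the form of the objective
  was fixed by that self-consistency requirement.  Parameters are
  normalized by the magnitudes of a data-driven starting guess, and the
  simplex is restarted (re-inflated) up to three times.

## Limitations

* The termination is linear and time-invariant by construction;
  nonlinear or adaptive downstream behaviour is out of scope.
* Model order must be chosen by the user; no automatic order selection
  is provided.
* Identification quality depends on the excitation: poles well outside
  the band excited by the inflow harmonics are not identifiable, and
  the reported fit can only be trusted over the excited band.
* The forward-Euler runtime is first-order accurate; at coarse solver
  steps its discretization error, not the fit, dominates the deployed
  accuracy.
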