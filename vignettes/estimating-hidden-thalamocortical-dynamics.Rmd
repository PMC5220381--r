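---
title: "Estimating hidden thalamocortical dynamics: model, reduction and filter design"
author: "thalatrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hidden thalamocortical dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalatrack)
```

## The scientific problem

Thalamocortical (TC) relay neurons forward sensorimotor cortical input to the
cortex. In Parkinson's disease, excessive inhibition from the globus pallidus
internus (GPi) de-inactivates the low-threshold T-type calcium current, and
the cell answers input with pathological rebound bursts instead of faithful
one-spike-per-pulse relay. The gating variables that carry this switch — the
sodium inactivation gate $h$ and the T-type calcium gate $w$ — cannot be
measured in an experiment; only the membrane potential can, and noisily.
This package provides the three pieces needed to reconstruct those hidden
properties in a form suitable for real-time use:

1. a reduced conductance-based TC relay model (`tc_parameters()`,
   `simulate_tc()`), used both as the data-generating "plant" and as the
   filter's internal model;
2. a cost-efficient variant of that model (`build_cetc()`) in which every
   nonlinear function is replaced by continuous piecewise-linear segments
   whose slopes are sums of at most three signed powers of two, so a digital
   datapath can evaluate them with barrel shifts and adds instead of
   multipliers;
3. a joint state-and-parameter unscented Kalman filter (`ukf_estimate()`)
   that assimilates the noisy voltage and returns $h$, $w$ and the injected
   current.

## The reduced TC relay model

The model keeps three state variables $(V, h, w)$:

$$C_m \dot V = -I_L - I_{Na} - I_K - I_T + I_{Gi \to Th} + I_{SM}$$

with $I_L = g_L (V - E_L)$,
$I_{Na} = g_{Na}\, m_\infty^3(V)\, h\,(V - E_{Na})$,
$I_K = g_K\, (c_K(1-h))^4 (V - E_K)$ and
$I_T = g_T\, p_\infty^2(V)\, w\, (V - E_T)$, and gate kinetics
$\dot h = a_h(V)(1-h) - b_h(V)h$,
$\dot w = (w_\infty(V) - w)/\tau_w(V)$.
Sodium activation is slaved to its steady state (it is far faster than $V$),
and potassium activation is tied to $1-h$; both reductions follow the
Terman/Rubin–Terman TC relay cell, whose published constants are the
defaults of `gating_functions()` and `tc_parameters()`. All constants are
configuration, not code, so alternative parameterizations (or a perturbed
plant) drop in.

Two deliberate choices in this layer:

* **Potassium coupling $c_K$.** The reduction is quoted in the literature
  both as $(1-h)^4$ and as $(0.75(1-h))^4$. We default to $c_K = 1$: with
  $c_K = 0.75$ the weakened spike after-hyperpolarization leaves the cell
  stuck on a depolarized plateau after the first rebound spike
  (depolarization block), and release from hyperpolarization produces a
  single spike rather than a burst. With $c_K = 1$ the cell shows the full
  phenotype set: silence at rest, tonic spiking under depolarizing steps
  with amplitude-dependent latency, 100% single-spike relay of a 25 ms
  square-wave drive in the normal regime, and multi-spike rebound bursts on
  release. Both variants remain available through `gating_functions(c_k=)`.
* **Parkinsonian GPi input.** A *constant* hyperpolarizing current at any
  level converts the cell into a 1:1 rebound relay — each stimulus pulse
  triggers exactly one rebound spike, never a burst. The Parkinsonian
  pallidum is not tonic, though: it fires low-frequency synchronized
  bursts. `gpi_spec("parkinsonian")` therefore applies phasic inhibition,
  $-1.5$ pA/µm² for the first 60% of a 100 ms cycle, calibrated once
  against the burst phenotype (≥ 2 spikes within 25 ms per event) and kept
  fixed thereafter. A constant level remains available via
  `gpi_spec("custom", level=)`.

Integration is explicit forward Euler at $\Delta t = 0.01$ ms. The kinetics
are non-stiff at this step (the fastest time constants are ≈ 0.1 ms at spike
peak); halving the step changes trajectories proportionally, the expected
first-order behavior, which the test suite asserts. Gates are clamped to
$[0,1]$ after every step. The initial state defaults to the rest state found
by a 5 s relaxation under the constant component of the inputs.

## The cost-efficient (CETC) function set

Eight scalar maps carry all the nonlinearity: $f_1 = m_\infty^3$,
$f_2 = p_\infty^2$, $f_3(h) = (c_K(1-h))^4$, $f_4 = h_\infty$, $f_5 = a_h$,
$f_6 = b_h$, $f_7 = w_\infty$, $f_8 = 1/\tau_w$. `fit_piecewise()` replaces
each by $n$ continuous linear pieces $K_i V + C_i$ under the hardware
constraint that every $K_i$ is exactly $\sum \pm 2^{s}$ with at most 3 terms
and shifts $s \in [-10, 4]$ (`quantize_slope()` enumerates the ≈ 4000
representable values exhaustively). Knots are placed by greedy refinement —
split the segment with the largest squared-error contribution at its
midpoint — because the sigmoids concentrate their curvature in a 20–30 mV
window and uniform knots would waste segments; after each refinement the
slopes are re-fit by least squares on a hinge basis, quantized, and polished
by coordinate descent over neighbouring representable values, with the free
offset re-optimized in closed form. The best fit seen is retained, so the
returned error is non-increasing in $n$ (asserted as a property test).
Defaults: 8 segments per function, domain $[-120, 20]$ mV (for $f_3$:
$h \in [0,1]$).

Fit quality is scored on $M = 1000$ uniform samples with three criteria
(`err_cf()`, `nerr_cf()`, `mae_cf()`): the RMS deviation, the RMS deviation
normalized by the range of the modified function (in percent), and the mean
absolute error. Note $\mathrm{MAE} \le \mathrm{ERR}_{CF}$ for any sample
set; the suite asserts this alongside the fits. `build_cetc()` bundles the
eight fits into a drop-in function set for `simulate_tc()` and
`ukf_estimate()` and attaches the per-function report; coefficient tables
can be exported/imported as CSV (`write_plf_tables()`, `read_plf_tables()`)
so that externally supplied segment tables can be used verbatim.

What "dynamics preserved" means here: spike *counts* match between the CETC
and original models under normal-mode stimulation, but pointwise RMS
deviations in $V$ are dominated by sub-millisecond spike-timing jitter
(a 0.5 ms shift of a 100 mV spike costs tens of mV of pointwise error), and
burst timing in the Parkinsonian regime is more sensitive still. The
dynamics-preservation tests therefore assert wide pointwise thresholds on
10,000-sample windows (normal: 20 mV / 0.2 / 0.05 for $V/h/w$; Parkinsonian:
25 mV / 0.3 / 0.3) together with the sharp spike-count equality.

## Filter design

The augmented state is $x = [I_{ext}, V, h, w]$, ordered so the observation
row $C = [0\,1\,0\,0]$ selects the voltage. $I_{ext}$ — the sum of pallidal
and sensorimotor input, which a dynamic-clamp application wants back — is a
random-walk parameter; $(V,h,w)$ advance one Euler step of the filter's
internal model per observation sample, each sigma point driven by its own
$I_{ext}$. The internal model defaults to the CETC set (what a hardware
realization runs); a flag selects the original closed forms.

**Sigma set.** The symmetric $2N$ set without a central point:
$\bar x \pm (\sqrt{N P})_{\mathrm{col}\,j}$, equal weights $1/(2N)$ — eight
points for $N = 4$, matching one parallel model-evaluation unit each in a
hardware pipeline. The set reproduces the generating mean and covariance
exactly (asserted on random SPD inputs), and makes the filter algebraically
exact on linear dynamics; the suite checks equality with a textbook Kalman
filter to 1e-6 over 1000 steps, and the compiled TC path against a plain-R
reference filter to 1e-9.

**Observation moments.** Because the observation is the linear functional
$Cx$, the predicted-observation mean, variance and cross-covariance are
taken directly from the a priori moments (process noise included) rather
than from a second pass over the points. This is what makes the
linear-system equivalence exact.

**Process-noise structure.** A scalar `Q` expands to
$\mathrm{diag}(Q, Q, 0, 10^{-8})$. The reasoning: the plant is
deterministic, so process noise exists (a) to let the random-walk parameter
move, and (b) to absorb model error in the voltage equation — hence $Q$ on
the first two components. Injecting comparable white noise into the gate
equations instead makes the weakly observable gates wander (an isotropic
$Q I_4$ at the operating point puts a random walk of ≈ 0.07/ms onto $w$,
an order of magnitude above its reconstruction error). The fast gate $h$ is
tightly slaved to voltage and needs no noise at all; the slow calcium gate
$w$ gets a small *fixed* variance floor ($10^{-8}$ per step, not scaled
with $Q$) that keeps its marginal variance from collapsing when $Q$ is
turned far down and reproduces the characteristic insensitivity of the $w$
error to the observation-noise setting. A full 4×4 `Q` overrides all of
this.

**Numerical safeguards.** The 4×4 Cholesky factorization adds escalating
diagonal jitter ($10^{-10}$, ×10 per retry, up to $10^{-4}$) before
declaring divergence; posterior covariances are re-symmetrized every step;
sigma-point gates are clamped to $[0,1]$ (configurable); a sigma point whose
voltage goes non-finite is pinned to the current estimate rather than
poisoning the ensemble. Defaults: $P_0 = I_4$,
$x_0 = [0, y_1, 0.5, 0.1]$ — uninformative but bounded.

**Operating points.** The square-wave estimation studies use
$Q = 5\times10^{-5}$, $R = 5$; the double-blind runs use $R = 1,
Q = 5\times10^{-3}$ (normal) and $R = 0.5, Q = 0.5$ (Parkinsonian). All
reported errors (`cf_rmse()`) drop the first 100 ms as filter settling.

## Observation noise and the robustness studies

`noise_spec()` generates Gaussian white noise, mains interference at 50 Hz,
its odd harmonic at 150 Hz, high-frequency interference at 350 Hz, and
their sum. "Strength" is a single axis: the Gaussian standard deviation and
the sinusoid amplitude, both in mV; sinusoid phases default to 0, making
those components deterministic. The mixture decomposes elementwise into its
four parts (asserted exactly). The sweep default is strengths
$\{0, 1, 2, 4\}$ mV — spanning sub-spike-height contamination up to several
times the Gaussian operating level.

Why 50 Hz hurts most: the filter separates observation noise from signal by
timescale. A 20 ms-period sinusoid is slow enough to be absorbed as genuine
voltage (or injected-current) variation, while 350 Hz averages out within a
few membrane time constants and white noise fastest of all. The mixture is
bounded below by its worst component.

## Study conditions and problem sizes

All experiment defaults are fixed once here and used identically by the
test suite and `scripts/acceptance.R`:

* plant: original closed-form model; filter: CETC; $\Delta t = 0.01$ ms;
* estimation runs: 2 s simulated time (200,001 samples), 100 ms burn-in,
  square-wave drive (25 ms period, 20% duty, 5 pA/µm²), Gaussian
  observation noise of 1 mV unless the noise itself is under study;
* sweeps: 20 repetitions per stochastic cell (deterministic sinusoid cells
  need only one), medians summarized with Tukey five-number statistics;
* Q/R grids: $R \in \{0.5, 5, 50, 500, 5000\}$ at $Q = 5\times10^{-5}$, and
  $Q \in \{5\times10^{-8}, \dots, 5\times10^{-4}\}$ at $R = 5$ — five
  decade-spaced points around the operating corner. Outside these ranges
  the error saturates at the open-loop level (large $R$, tiny $Q$) or at
  the model-mismatch floor (tiny $R$, large $Q$) and median ordering
  degenerates into ties, so the grids cover the regime where the filter
  actually responds;
* double-blind: plant conductances jittered by ±10% multiplicative uniform
  factors and sigmoid half-voltages shifted by up to ±10% of their slope
  factors; drive = gamma pulse train (30 Hz mean rate, CV 0.2, 5 pA/µm²,
  5 ms pulses); the filter uses the unperturbed defaults and sees only the
  noisy voltage. The no-filter baseline for $w$ is $w_\infty$ applied to
  the observed voltage.

The spike counter (`detect_spikes()`) uses a −20 mV upward-crossing
threshold with a 2 ms refractory merge; burst events are ≥ 2 spikes within
25 ms. These are artifact conventions — the underlying phenomena are not
threshold-sensitive in any range we examined between −30 and −10 mV.

## What the synthetic data do and do not emulate

All inputs are synthetic by design: the plant is the package's own
simulator, so the "truth" for every hidden variable is known exactly and
estimation error can be measured directly — the point of the evaluation
protocol. The generator emulates irregular cortical drive (gamma pulse
trains), pathological pallidal rhythms, measurement noise of realistic
spectral composition, and — through the double-blind protocol — parameter
uncertainty between the recorded cell and the filter's model. It does not
emulate electrode drift or access-resistance artifacts, spike-frequency
adaptation currents absent from the reduced model, channel noise, or
multi-compartment effects. Passing tests therefore demonstrate correctness
and robustness of the estimator *given* a cell in this model class with
perturbed parameters; they cannot certify performance on real recordings,
where unmodelled currents would be absorbed into the reconstructed
$I_{ext}$ (visible here already as the plateau bias of the injected-current
estimate under the perturbed plant, bounded in the tests at 1 pA/µm²).

## Known limitations

* Forward Euler only (a deliberate match to the digital-hardware context);
  no implicit or adaptive integration.
* The piecewise-linear fitter is greedy; it makes no optimality claim
  beyond monotone improvement and the measured sub-2% normalized error.
* Scalar observations only (one electrode); no smoothing, no square-root
  filter variants, no adaptive noise tuning.
* The fixed-point layer (`fixed_cholesky()`, `fixed_evaluate_plf()`)
  emulates word-length effects of a hardware datapath at the arithmetic
  level; it is not a cycle-accurate pipeline model.
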