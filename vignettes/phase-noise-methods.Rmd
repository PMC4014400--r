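---
title: "Methods: the phase model, noise-regression PRC estimation, and spike-time variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the phase model, noise-regression PRC estimation, and spike-time variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prcnoise)
```

## The model and its assumptions

A repetitively firing neuron near its limit cycle is reduced to a single
variable, the phase φ, which advances from 0 (the last spike) to 1 (the next
firing point):

$$\frac{d\varphi}{dt} = \omega + Z(\varphi)\, I_\mathrm{stim}(t)$$

ω (spikes/ms) is the unperturbed firing rate and Z(φ) (cycles per pA·ms) the
infinitesimal phase-resetting curve: the phase advance per unit injected
charge as a function of the phase at which the charge arrives. The model
assumes perturbations are weak enough that the cell never strays far from
its limit cycle, so their entire effect is a change of position along it.
Positive and negative currents act with equal magnitude and opposite sign;
two inputs in one interval combine additively through their phase shifts.
All cell-specific dynamics — afterhyperpolarization currents, persistent
inward currents, the shape of the interspike membrane-potential trajectory —
are folded into the single function Z.

The package works throughout with *type-1* curves (Z ≥ 0 everywhere), the
form observed in autonomously firing basal-ganglia neurons, but nothing in
the estimator or the simulator requires nonnegativity.

### Stimulus model

The perturbation is *pulsed Gaussian noise*: contiguous rectangular current
pulses of fixed duration d (ms) whose amplitudes are i.i.d. draws from
N(0, σ²) (σ in pA). Pulses rather than band-limited white noise make the
delivered charge directly verifiable in an experiment (see
`pulse_slope_qc()`): within a well-compensated recording, each pulse should
produce a near-linear voltage ramp of slope proportional to its amplitude
(slope = I/C for an ideal capacitance C). The check reports per-pulse
slopes, the slope-vs-amplitude regression coefficient and its R², and leaves
any pass/fail threshold to the user, since acceptable linearity depends on
the recording configuration.

## Simulation

`simulate_trajectory()` integrates the phase equation with the first-order
(Euler) update

$$\varphi_{t+\Delta t} = \varphi_t + \Delta t\,\big(\omega + Z(\varphi_t)\,I(t)\big)$$

with the current held constant within each of its recorded samples. Z is the
piecewise-linear interpolant through the tabulated bin centers with pinned
endpoints Z(0) = Z(1) = 0, and Z(φ) = 0 for φ > 1 (charge delivered after
the crossing cannot affect the interval that produced it).

Numerical choices:

* **Crossing convention.** By default a spike is recorded at the first grid
  time with φ ≥ 1, matching a discrete-time acquisition view. With
  `refine = TRUE` the crossing is linearly interpolated within the final
  step, which makes the zero-noise interval exactly 1/ω and is used when an
  exact self-consistency oracle is wanted. Either way, halving Δt changes
  the zero-noise interval by at most one step (first-order convergence; this
  is asserted in the test suite).
* **Restart vs drift.** In `mode = "restart"` φ resets to 0 at each
  crossing, generating a spike train under continuing input — the data
  generator's convention. In `mode = "drift"` only the first crossing is
  recorded; the input is then disconnected and φ advances at ω alone, so
  phases above 1 map exactly onto time since the spike. The drift convention
  is used for Monte Carlo ensembles, where the distribution of first
  crossing times *is* the interspike-interval distribution and a vertical
  slice through the trajectories at any time is the latent-phase
  distribution (`phase_distribution_at()`).
* **Negative phase.** A large negative pulse where Z is large can push φ
  below 0, a region where the model is silent. φ is clamped at 0 and the
  event counted (`n_clamped`); at the package's default scales clamping is
  essentially never triggered because type-1 curves vanish near φ = 0.
* **Seeding.** Ensemble trajectory i draws its noise from seed
  `seed + i − 1`, so ensembles are bit-reproducible and independent of
  execution order. The inner Euler loop is compiled (Rcpp); ensembles are
  advanced vectorised across trajectories in R.
* **Default scales.** Monte Carlo experiments default to the period-1000 ms,
  Δt = 1 ms, 5000-trajectory configuration used for the ensemble figures;
  the test suite uses 3000–5000 trajectories and horizons of 3–10 mean
  periods (longer where heavy noise skews the ISI distribution) to keep the
  full suite around two minutes.

## PRC estimation from injected noise

`estimate_prc()` implements the charge-matrix multiple regression. Each
interspike interval α is divided into n equal phase bins; the charge
delivered in bin i is

$$Q_{\alpha i} = \sum_{t \,\in\, \mathrm{bin}\ i} I(t)\,\Delta t
\quad (\mathrm{pA\,ms}),$$

and the normalized duration $y_\alpha = T_\alpha/\bar T$ is regressed on the
n charge columns by ordinary least squares with a freely estimated
intercept:

$$y_\alpha = \beta_0 - \sum_i Z(\varphi_i)\, Q_{\alpha i} + \varepsilon_\alpha .$$

Charge that advances phase shortens the interval, so the PRC values are the
negated coefficients. Details and choices:

* **Bin count.** n = mean ISI / d, capped at 50 (`choose_n_bins()`): on
  average one noise pulse per bin, keeping the charge regressors
  statistically independent. A guard requires at least n + 10 intervals.
* **Time-to-phase mapping.** *Interpolated phase* (default) maps each time
  to the fraction of its own interval elapsed; every sample lands in a bin
  and row sums conserve the injected charge. *Mean-period* binning maps time
  since the previous spike through the average period; samples mapping past
  bin n (intervals longer than the mean) are discarded. Each current sample
  is assigned to the bin containing its start time, so a pulse straddling a
  bin edge is split by sample membership.
* **Why interpolated phase.** Latent phase drifts away from elapsed time in
  direct proportion to how effective the noise is; under mean-period
  binning this drift concentrates estimation error at late phases, where
  the accumulated phase variance is largest. Interpolated phase is exact at
  both ends of every interval and distributes the residual error evenly.
  On matched simulated data the mean regression SE under mean-period
  binning is more than twice that under interpolated-phase binning, with
  the gap concentrated in the late-phase bins — this is the package's
  headline acceptance quantity (`scripts/acceptance.R`).
* **Standard errors and R².** SEs are the classical OLS coefficient
  standard errors, i.e. residual variance times the diagonal of
  (X′X)⁻¹, square-rooted — the residual-variance factor is included
  deliberately, favouring statistical correctness. R² is the
  multiple-regression coefficient of determination: the proportion of ISI
  variance attributable to the injected noise, which saturates at the
  intrinsic-noise ceiling in real (or synthetic two-noise) cells.
* **Intercept.** Estimated freely (expected ≈ 1 for normalized intervals)
  rather than fixed at 1, so slow rate drift is absorbed without biasing Z.
  The normalizing $\bar T$ is the mean interval of the episode being fitted.
* **Summary metrics.** `sensitivity()` computes S = ∫₀¹Z² on the
  pinned-endpoint piecewise-linear interpolant using the exact per-segment
  closed form (the square of a linear segment is quadratic), so a
  triangular curve of height h integrates to h²/3 exactly. `centroid()` is
  the first moment Σφᵢ Zᵢ / ΣZᵢ over the tabulated bins.

### Known limitation: attenuation at high CV

Interpolated phase is a first-order proxy for latent phase. As the
perturbation grows (ISI CV beyond roughly 0.2), the residual discrepancy
between the two acts as an errors-in-variables perturbation of the
regressors and the estimated curve is mildly attenuated toward zero — a
bias that does not shrink with recording length, so with very long episodes
it eventually exceeds the (ever-shrinking) standard errors. The test suite
therefore checks parameter recovery in the small-perturbation regime where
the method is designed to operate — a low-sensitivity cell
(S = 1×10⁻⁷ cycles²/(pA²·ms²), the bottom of the observed range) firing at
20 spikes/s, for which σ = 60 pA gives CV ≈ 0.13 — and checks, at fixture
scale, that the recovered sensitivity is stable across σ = 40–100 pA and
that R² rises then saturates with σ. Estimates made at large CV remain
useful for prediction (the worked example in the README predicts 90% of the
spike-time variance with a curve estimated at CV 0.37) but their amplitude
should not be read as unbiased.

## Predicting variability: the CV approximation

For small noise, the variance of the latent-phase distribution grows along
the mean trajectory as the accumulated noise variance weighted by Z²; with
pulsed noise, each pulse contributes an effective variance d²σ² and an
average interval contains 1/(dω) pulses, so charge variance accumulates at
rate dσ²/ω per interval. The phase variance at time t after a spike is

$$\mathrm{Var}(t) = \frac{d\,\sigma^2}{\omega}\int_0^{\omega t} Z(u)^2\,du,$$

and because interval variance equals the phase variance at t = 1/ω scaled
by 1/ω², the coefficient of variation is

$$\mathrm{CV} = \sigma \sqrt{\frac{d\, S}{\omega}},\qquad S = \int_0^1 Z^2 .$$

CV is exactly linear in σ, grows as √d and falls as 1/√ω; the test suite
verifies all three exponents against Monte Carlo ensembles (log–log slopes
0.5 and −0.5 within ±0.05). The approximation assumes the phase
distribution stays narrow enough that Z at the mean phase represents the
whole distribution; sweeping σ upward at 1 spike/s with the raised-cosine
fixture curve, the acceptance suite locates the breakdown at a Monte Carlo
CV of about 0.4 (15% relative error). No spectral correction beyond the
d²σ² pulse-variance conversion is applied — the finite pulse bandwidth is
accounted for entirely by that factor.

## Spike-time prediction

`predict_spike_times()` restarts the phase model at each recorded spike
(φ = 0), integrates the *recorded* current with a fine step
(Δt = 0.05 ms by default, with sub-step crossing interpolation), and takes
the crossing of φ = 1 as the predicted next spike. ω defaults to the
reciprocal of the mean ISI of the episode being predicted — the cell's own
average rate during that episode — and can be overridden. Accuracy is
scored as the sum-of-squares variance explained, 1 − SSres/SStot, about the
mean actual interval; unlike the squared Pearson correlation (also
available) it penalizes bias. If φ fails to cross within five mean periods
(possible only under sustained strongly negative drive) the interval is
reported unpredicted rather than extrapolated.

## The synthetic-experiment generator

`synth_experiment()` stands in for noise-injection recordings from an
autonomously firing neuron. Each episode is a restart-mode simulation driven
by the sum of two independent pulsed-noise currents through the same PRC:
the injected noise (exposed to estimators) and a hidden *intrinsic* noise
representing the cell's own spike-time jitter. Modelling intrinsic
variability as a hidden current through the same curve (rather than as
additive ISI jitter) preserves the variance partition of the phase model,
so the expected regression R² is analytically σ²/(σ² + σ²ᵢₙₜ) — the
generator's calibration is itself checkable, and the test suite confirms
R² ≈ 0.5 when the two variances are equal.

Defaults, chosen once to describe a typical recorded cell:

| parameter | default | rationale |
|---|---|---|
| firing rate | 12 spikes/s | middle of the observed 4.5–31.9 spikes/s range |
| PRC | raised cosine, S = 4×10⁻⁷ | mid-range of observed sensitivities (10⁻⁷–10⁻⁶) |
| injected noise | σ = 60 pA, d = 0.5 ms | the stimulus at which estimates become reliable |
| intrinsic noise | 30 pA | injected share of ISI variance 60²/(60²+30²) = 0.8 |
| episode length | 60 s | one acquisition episode |

With these defaults the baseline (noise-free) CV is ≈ 0.12, inside the
observed 0.04–0.35 resting range, and estimation on one episode followed by
prediction of a second yields variance explained around 0.7 (the end-to-end
test asserts the interval [0.6, 0.9] over 20 replicates). The beta-family
shapes (`make_type1_prc(family = "beta")`) provide early- and late-peaked
type-1 curves for shape-sensitivity experiments; predicting with a generic
raised cosine rescaled to the correct sensitivity is measurably worse than
predicting with the estimated curve when the ground truth is skewed.

What the generator does *not* emulate: conductance-based spike dynamics,
spike-frequency adaptation and the rate-dependent reshaping of the PRC under
constant-current drive, correlated (non-white) intrinsic noise, and
measurement artefacts (electrode filtering, series-resistance error).
Passing tests on these fixtures therefore demonstrates the correctness of
the estimator and the theory under the phase model's own assumptions, not
robustness to every way a real recording can violate them. The
intrinsic-noise structure of real cells is uncharacterized; the
hidden-current model is one defensible choice and is documented as such.

## Degenerate inputs and tie-breaks

* Traces must be finite and uniformly sampled; the two-column reader
  rejects timestamp jitter beyond a relative tolerance of 10⁻⁶, naming the
  offending row.
* `detect_spikes()` takes the first sample at/above threshold per upward
  crossing (no sub-sample interpolation) and errors if the threshold is at
  or below the trace minimum.
* `bin_charges()` errors if any interval is shorter than one current
  sample; in interpolated mode a rounding guard assigns a sample at phase
  exactly 1 to the last bin.
* `fit_prc()` requires at least n + 2 intervals (the wrapper, n + 10) and
  reports the offending columns on rank deficiency.
* `centroid()` is undefined for an all-zero curve and errors rather than
  returning NaN.
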