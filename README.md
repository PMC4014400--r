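# prcnoise

Phase-resetting-curve estimation and spike-time prediction for repetitively
firing neurons densely perturbed by current noise.

Many neurons — subthalamic nucleus (STN) projection neurons are the canonical
example — fire rhythmically on their own. Subthreshold inputs to such a cell
do not insert or delete spikes; they shift the timing of spikes that would
have occurred anyway. Near its limit cycle the cell reduces to a phase
oscillator

    dφ/dt = ω + Z(φ) · I(t)

where φ ∈ [0, 1) is the phase of the firing cycle (φ = 1 is the firing
point), ω is the unperturbed firing rate, I(t) the injected current, and
Z(φ) the infinitesimal phase-resetting curve (PRC) — the phase advance per
unit charge, as a function of the phase at which the charge arrives.

`prcnoise` is a toolkit for working with this model when the stimulus is
*pulsed Gaussian noise*: contiguous current pulses of fixed duration d (ms)
whose amplitudes are i.i.d. zero-mean Gaussian with SD σ (pA). It provides:

* **Simulation** — single trajectories and Monte Carlo ensembles of the
  phase model under pulsed noise (`simulate_trajectory()`,
  `simulate_ensemble()`, `phase_distribution_at()`), with a compiled Euler
  core.
* **PRC estimation from noise** — the charge-matrix multiple-regression
  estimator (`estimate_prc()`): each interspike interval is divided into
  equal phase bins, the charge delivered in each bin is a regressor, and the
  normalized interval duration is the response; the negated coefficients are
  the PRC with per-bin standard errors and an R² giving the share of ISI
  variance attributable to the injected noise. Phase may be mapped by each
  interval's own length (*interpolated phase*, the default) or by the mean
  period.
* **Variability theory** — the closed-form prediction of the coefficient of
  variation of interspike intervals,

      CV = σ · sqrt(d · S / ω),   S = ∫₀¹ Z(φ)² dφ  (the Sensitivity),

  plus the running-integral approximation for the growth of latent-phase
  variance through the interval (`predicted_cv()`,
  `phase_variance_evolution()`, `cv_curve()`).
* **Spike-time prediction** — restart the phase model at each recorded spike
  and integrate the recorded current to predict the next spike
  (`predict_spike_times()` or `predict()` on a fitted object), scored as the
  proportion of ISI variance explained.
* **Spike-train statistics** — ISI CV, autocorrelogram, mean rate.
* **Synthetic experiments** — a ground-truth generator
  (`synth_experiment()`) emulating noise-injection recordings from an
  autonomously firing cell, including a hidden intrinsic noise source, and a
  one-call pipeline (`run_pipeline()`).
* **Trace I/O and QC** — delimited-text readers/writers for current and
  voltage traces, spike trains and PRC tables; threshold spike detection;
  the pulse-slope linearity check for verifying charge delivery
  (`pulse_slope_qc()`).

A command-line front end with subcommands
`simulate | estimate-prc | predict | cv-curve | stats | make-fixture | run`
is installed at `inst/cli/prcnoise`.

## Worked example

Estimate a PRC from a noise-perturbed spike train and use it to predict the
same cell's firing:

```r
library(prcnoise)
# ground-truth cell: type-1 PRC (sensitivity 4e-7), 10 spikes/s
truth <- make_type1_prc(sensitivity_target = 4e-7)
noise <- generate_pulsed_noise(sigma = 60, d = 1, duration = 60000, dt = 1, seed = 1)
cell  <- simulate_trajectory(truth, omega = 0.01, current = noise, record_phase = FALSE)
c(rate = mean_rate(cell$spikes), cv = isi_cv(cell$spikes))
#>      rate        cv
#> 9.7939264 0.3717043

fit <- estimate_prc(noise, cell$spikes, d = 1)
fit
#> PRC estimate by charge-matrix regression
#>   binning     : interpolated phase, 50 bins
#>   intervals   : 586 (mean ISI 102.1 ms)
#>   R^2         : 0.9110   intercept: 0.9569 (SE 0.0058)
#>   sensitivity : 2.983e-07 cycles^2/(pA^2 ms^2)
#>   peak Z      : 0.000917 cycles/(pA ms) at phase 0.550
```

The noise-driven firing is irregular (CV 0.37) at an unchanged mean rate;
the regression attributes 91% of the ISI variance to the injected noise, and
the recovered curve is type 1 with its peak mid-cycle. The fitted
sensitivity feeds the closed-form variability prediction, and the fitted
curve predicts spike times:

```r
predicted_cv(sigma = 60, d = 1, omega = 0.01, sensitivity = sensitivity(fit$prc))
#> [1] 0.3277137

predict(fit, noise, cell$spikes)
#> Spike-time prediction from the phase model
#>   intervals          : 586 (0 unpredicted)
#>   variance explained : 0.9046
#>   omega              : 0.00979393 spikes/ms (dt = 0.05 ms)
```

At this noise level the estimated curve is mildly attenuated relative to the
generating one (see the methods vignette on the interpolated-phase
approximation), yet it still accounts for 90% of the spike-time variance.

Units package-wide: time ms, current pA, voltage mV, charge pA·ms, phase in
cycles (0–1), rate ω in spikes/ms internally (the CLI accepts spikes/s).

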